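// Local alignment kernels shared by the ANI, dereplication, pangenome-graph
// and read-recruitment stages. All alignments are Smith-Waterman with affine
// gaps (gap of length k costs open + k*extend). Scoring matrices are passed
// in from R: 5x5 for nucleotides (A,C,G,T,N; N never matches anything), 27x27
// for amino acids (A..Z plus '*').
//
// Seeded paths (k-mer candidate selection + windowed DP) exist for the batch
// entry points; each has an exact mode that runs the full DP so the seeded
// result can be checked against it.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

// ---- encoding ----------------------------------------------------------

static inline int enc_nt(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and anything else
  }
}

static inline int enc_aa(char c) {
  if (c >= 'A' && c <= 'Z') return c - 'A';
  if (c >= 'a' && c <= 'z') return c - 'a';
  return 26; // '*' and anything else
}

static std::vector<int> encode_seq(const std::string& s, bool aa) {
  std::vector<int> v(s.size());
  if (aa) for (size_t i = 0; i < s.size(); ++i) v[i] = enc_aa(s[i]);
  else    for (size_t i = 0; i < s.size(); ++i) v[i] = enc_nt(s[i]);
  return v;
}

struct ScoreMat {
  std::vector<int> m;
  int n;
  ScoreMat(const IntegerMatrix& im) : n(im.nrow()) {
    m.resize(n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) m[i * n + j] = im(i, j);
  }
  inline int at(int a, int b) const { return m[a * n + b]; }
};

// ---- full DP with traceback -------------------------------------------

struct AlnStats {
  int score = 0;
  int qstart = 0, qend = -1, sstart = 0, send = -1; // 0-based inclusive
  int matches = 0;       // identical residue pairs
  int pairs = 0;         // residue-residue columns (gaps excluded)
  int cols = 0;          // total alignment columns
};

// Traceback byte layout: bits 0-1 = H move (0 stop, 1 diag, 2 from E, 3 from F),
// bit 2 = E opened here, bit 3 = F opened here.
// aa=false applies the nucleotide rule that N (code 4) never counts as a
// match even against another N; aa=true counts plain residue equality.
static AlnStats sw_full(const std::vector<int>& q, const std::vector<int>& s,
                        const ScoreMat& sm, int gapO, int gapE,
                        bool aa = false) {
  const int m = (int)q.size(), n = (int)s.size();
  AlnStats best;
  if (m == 0 || n == 0) return best;
  std::vector<int> Hv(n + 1, 0), Fv(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1));
  int* H = Hv.data();
  int* F = Fv.data();
  const int* sp = s.data();
  const int open = gapO + gapE;
  int besti = 0, bestj = 0, bestscore = 0;
  for (int i = 1; i <= m; ++i) {
    const int* srow = &sm.m[q[i - 1] * sm.n];
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    int hdiag = 0;   // H[i-1][j-1], updated in place
    int e = NEG_INF; // E for current row
    for (int j = 1; j <= n; ++j) {
      const int hup = H[j]; // H[i-1][j]
      uint8_t flag = 0;
      const int eo = H[j - 1] - open;
      e -= gapE;
      if (eo >= e) { e = eo; flag = 4; }
      const int fo = hup - open;
      int f = F[j] - gapE;
      if (fo >= f) { f = fo; flag |= 8; }
      F[j] = f;
      int h = hdiag + srow[sp[j - 1]];
      hdiag = hup;
      uint8_t mv = 1;
      if (e > h) { h = e; mv = 2; }
      if (f > h) { h = f; mv = 3; }
      if (h <= 0) { h = 0; mv = 0; }
      H[j] = h;
      tbrow[j] = (uint8_t)(mv | flag);
      if (h > bestscore) { bestscore = h; besti = i; bestj = j; }
    }
  }
  best.score = bestscore;
  if (best.score <= 0) return best;
  // traceback
  int i = besti, j = bestj;
  best.qend = besti - 1; best.send = bestj - 1;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int mv = t & 3;
      if (mv == 0) break;
      if (mv == 1) {
        best.cols++; best.pairs++;
        if (q[i - 1] == s[j - 1] && (aa || q[i - 1] != 4)) best.matches++;
        --i; --j;
      } else if (mv == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap in query, consumed subject char j
      best.cols++;
      bool opened = (t & 4) != 0;
      --j;
      if (opened) state = 0;
    } else { // F: gap in subject, consumed query char i
      best.cols++;
      bool opened = (t & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }
  best.qstart = i; best.sstart = j; // 0-based starts (i,j are counts consumed before)
  return best;
}

static List stats_to_list(const AlnStats& a) {
  return List::create(
    _["score"] = a.score,
    _["qstart"] = a.qstart + 1, _["qend"] = a.qend + 1,
    _["sstart"] = a.sstart + 1, _["send"] = a.send + 1,
    _["matches"] = a.matches, _["pairs"] = a.pairs, _["cols"] = a.cols);
}

// ---- exported single-pair alignment ------------------------------------

// [[Rcpp::export]]
List cpp_align(std::string q, std::string s, IntegerMatrix mat,
               int gap_open, int gap_extend, bool aa) {
  std::vector<int> qe = encode_seq(q, aa), se = encode_seq(s, aa);
  ScoreMat sm(mat);
  AlnStats a = sw_full(qe, se, sm, gap_open, gap_extend, aa);
  return stats_to_list(a);
}

// ---- batch pair alignment ----------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_align_pairs(CharacterVector seqs, IntegerVector qi, IntegerVector si,
                          IntegerMatrix mat, int gap_open, int gap_extend, bool aa) {
  int np = qi.size();
  ScoreMat sm(mat);
  std::vector<std::vector<int> > enc(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    enc[i] = encode_seq(as<std::string>(seqs[i]), aa);
  IntegerVector score(np), qstart(np), qend(np), sstart(np), send(np),
    matches(np), pairs(np), cols(np);
  for (int p = 0; p < np; ++p) {
    AlnStats a = sw_full(enc[qi[p] - 1], enc[si[p] - 1], sm, gap_open, gap_extend, aa);
    score[p] = a.score; qstart[p] = a.qstart + 1; qend[p] = a.qend + 1;
    sstart[p] = a.sstart + 1; send[p] = a.send + 1;
    matches[p] = a.matches; pairs[p] = a.pairs; cols[p] = a.cols;
  }
  return DataFrame::create(_["score"] = score, _["qstart"] = qstart,
    _["qend"] = qend, _["sstart"] = sstart, _["send"] = send,
    _["matches"] = matches, _["pairs"] = pairs, _["cols"] = cols);
}

// [[Rcpp::export]]
NumericVector cpp_self_scores(CharacterVector seqs, IntegerMatrix mat, bool aa) {
  ScoreMat sm(mat);
  NumericVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::vector<int> e = encode_seq(as<std::string>(seqs[i]), aa);
    long s = 0;
    for (size_t j = 0; j < e.size(); ++j) s += sm.at(e[j], e[j]);
    out[i] = (double)s;
  }
  return out;
}

// ---- k-mer machinery ----------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static bool kmer_code(const std::vector<int>& e, int pos, int k, int alpha,
                      uint64_t* code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int v = e[pos + i];
    if (alpha == 5 && v == 4) return false; // skip k-mers containing N
    c = c * (uint64_t)alpha + (uint64_t)v;
  }
  *code = c;
  return true;
}

static KmerIndex build_index(const std::vector<std::vector<int> >& enc,
                             int k, int alpha) {
  KmerIndex idx;
  for (size_t s = 0; s < enc.size(); ++s) {
    const std::vector<int>& e = enc[s];
    if ((int)e.size() < k) continue;
    uint64_t code;
    for (int p = 0; p + k <= (int)e.size(); ++p) {
      if (!kmer_code(e, p, k, alpha, &code)) continue;
      std::vector<int>& v = idx[code];
      if (v.empty() || v.back() != (int)s) v.push_back((int)s);
    }
  }
  return idx;
}

// Unordered candidate pairs (1-based, i < j) sharing at least one k-mer.
// [[Rcpp::export]]
DataFrame cpp_kmer_pairs(CharacterVector seqs, int k, bool aa) {
  int alpha = aa ? 27 : 5;
  std::vector<std::vector<int> > enc(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    enc[i] = encode_seq(as<std::string>(seqs[i]), aa);
  KmerIndex idx = build_index(enc, k, alpha);
  std::vector<std::pair<int,int> > pairs;
  {
    std::unordered_map<uint64_t, char> seen; // pair key -> present
    for (KmerIndex::const_iterator it = idx.begin(); it != idx.end(); ++it) {
      const std::vector<int>& v = it->second;
      if (v.size() < 2) continue;
      for (size_t a = 0; a < v.size(); ++a)
        for (size_t b = a + 1; b < v.size(); ++b) {
          uint64_t key = ((uint64_t)v[a] << 32) | (uint64_t)v[b];
          if (seen.insert(std::make_pair(key, 1)).second)
            pairs.push_back(std::make_pair(v[a], v[b]));
        }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerVector pi(pairs.size()), pj(pairs.size());
  for (size_t p = 0; p < pairs.size(); ++p) {
    pi[p] = pairs[p].first + 1; pj[p] = pairs[p].second + 1;
  }
  return DataFrame::create(_["i"] = pi, _["j"] = pj);
}

// Positional index of one subject sequence: k-mer -> positions.
typedef std::unordered_map<uint64_t, std::vector<int> > PosIndex;

static PosIndex build_pos_index(const std::vector<int>& e, int k, int alpha) {
  PosIndex idx;
  uint64_t code;
  for (int p = 0; p + k <= (int)e.size(); ++p) {
    if (!kmer_code(e, p, k, alpha, &code)) continue;
    idx[code].push_back(p);
  }
  return idx;
}

// Best diagonal bucket (by seed votes) of query against a positional index.
// Returns votes; writes the representative diagonal (subject_pos - query_pos).
static int best_diagonal(const std::vector<int>& q, const PosIndex& idx,
                         int k, int alpha, int* diag_out) {
  std::unordered_map<int, int> votes;
  uint64_t code;
  const int bucket = 32;
  for (int p = 0; p + k <= (int)q.size(); ++p) {
    if (!kmer_code(q, p, k, alpha, &code)) continue;
    PosIndex::const_iterator it = idx.find(code);
    if (it == idx.end()) continue;
    const std::vector<int>& pos = it->second;
    for (size_t z = 0; z < pos.size(); ++z) {
      int d = pos[z] - p;
      votes[d >= 0 ? d / bucket : -((-d + bucket - 1) / bucket)]++;
    }
  }
  int best = 0, bestb = 0;
  for (std::unordered_map<int,int>::const_iterator it = votes.begin();
       it != votes.end(); ++it) {
    if (it->second > best || (it->second == best && it->first < bestb)) {
      best = it->second; bestb = it->first;
    }
  }
  *diag_out = bestb * 32;
  return best;
}

// ---- fragment ANI -------------------------------------------------------

// Directional fragment ANI of genome A against genome B. A is cut into
// consecutive fragments of frag_len (trailing remainder kept); each fragment
// is aligned to B (both strands; seeded window unless exact) and kept if
// percent identity >= min_id and fragment coverage >= min_cov.
// [[Rcpp::export]]
DataFrame cpp_ani_fragments(std::string genomeA, std::string genomeB,
                            std::string genomeB_rc, int frag_len,
                            IntegerMatrix mat, int gap_open, int gap_extend,
                            int seed_k, int margin, bool exact) {
  ScoreMat sm(mat);
  std::vector<int> A = encode_seq(genomeA, false);
  std::vector<int> Bf = encode_seq(genomeB, false);
  std::vector<int> Br = encode_seq(genomeB_rc, false);
  PosIndex idxF, idxR;
  if (!exact) {
    idxF = build_pos_index(Bf, seed_k, 5);
    idxR = build_pos_index(Br, seed_k, 5);
  }
  int nfrag = (int)((A.size() + frag_len - 1) / frag_len);
  NumericVector identity(nfrag), coverage(nfrag);
  IntegerVector flen(nfrag), score(nfrag);
  for (int f = 0; f < nfrag; ++f) {
    int start = f * frag_len;
    int len = std::min(frag_len, (int)A.size() - start);
    std::vector<int> frag(A.begin() + start, A.begin() + start + len);
    flen[f] = len;
    AlnStats best;
    if (exact) {
      AlnStats af = sw_full(frag, Bf, sm, gap_open, gap_extend);
      AlnStats ar = sw_full(frag, Br, sm, gap_open, gap_extend);
      best = (ar.score > af.score) ? ar : af;
    } else {
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int>& B = strand == 0 ? Bf : Br;
        const PosIndex& idx = strand == 0 ? idxF : idxR;
        int diag;
        int votes = best_diagonal(frag, idx, seed_k, 5, &diag);
        if (votes == 0) continue;
        int ws = std::max(0, diag - margin);
        int we = std::min((int)B.size(), diag + 32 + len + margin);
        if (we <= ws) continue;
        std::vector<int> win(B.begin() + ws, B.begin() + we);
        AlnStats a = sw_full(frag, win, sm, gap_open, gap_extend);
        if (a.score > best.score) best = a;
      }
    }
    if (best.score > 0 && best.pairs > 0) {
      identity[f] = 100.0 * best.matches / best.pairs;
      coverage[f] = (double)(best.qend - best.qstart + 1) / len;
      score[f] = best.score;
    } else {
      identity[f] = 0.0; coverage[f] = 0.0; score[f] = 0;
    }
  }
  return DataFrame::create(_["fragment"] = seq(1, nfrag), _["length"] = flen,
    _["identity"] = identity, _["coverage"] = coverage, _["score"] = score);
}

// ---- read recruitment ---------------------------------------------------

// Best-gene assignment of reads against a gene catalog. Candidate genes per
// strand are located by shared seed k-mers with diagonal voting (top
// max_cand genes aligned inside a window around their best diagonal); exact
// mode aligns every read against every gene on both strands. Acceptance:
// identity >= min_id (percent) and read coverage >= min_cov (fraction).
// Ties broken by identity, then alignment length (columns), then gene order.
// [[Rcpp::export]]
DataFrame cpp_recruit(CharacterVector reads, CharacterVector reads_rc,
                      CharacterVector genes, int seed_k, IntegerMatrix mat,
                      int gap_open, int gap_extend, double min_id,
                      double min_cov, int max_cand, bool exact) {
  ScoreMat sm(mat);
  const int ng = genes.size(), nr = reads.size();
  const int bucket = 32, margin = 24;
  std::vector<std::vector<int> > G(ng);
  for (int g = 0; g < ng; ++g) G[g] = encode_seq(as<std::string>(genes[g]), false);
  // positional k-mer index over all genes: kmer -> packed (gene, pos);
  // packing limits: < 8192 genes of < 256 kb each (plenty for gene catalogs)
  if (!exact && ng >= 8192)
    stop("seeded recruitment supports at most 8191 catalog genes");
  KmerIndex idx;
  if (!exact) {
    for (int g = 0; g < ng; ++g)
      if ((int)G[g].size() >= (1 << 18))
        stop("seeded recruitment supports genes shorter than 256 kb");
    uint64_t code;
    for (int g = 0; g < ng; ++g)
      for (int p = 0; p + seed_k <= (int)G[g].size(); ++p) {
        if (!kmer_code(G[g], p, seed_k, 5, &code)) continue;
        idx[code].push_back((int)(((uint64_t)g << 18) | (uint64_t)p));
      }
  }
  std::vector<int> r_read, r_gene, r_alnlen, r_sstart, r_send, r_strand;
  std::vector<double> r_ident, r_qcov;
  std::unordered_map<uint64_t, int> votes;
  struct Cand { int gene; int diag; int votes; };
  for (int r = 0; r < nr; ++r) {
    std::vector<int> enc_f = encode_seq(as<std::string>(reads[r]), false);
    std::vector<int> enc_r = encode_seq(as<std::string>(reads_rc[r]), false);
    const int rlen = (int)enc_f.size();
    double best_id = -1.0; int best_gene = -1, best_cols = -1, best_strand = 0;
    AlnStats best;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& q = strand == 0 ? enc_f : enc_r;
      std::vector<Cand> cand;
      if (exact) {
        for (int g = 0; g < ng; ++g) {
          Cand c; c.gene = g; c.diag = -1; c.votes = 0;
          cand.push_back(c);
        }
      } else {
        votes.clear();
        uint64_t code;
        for (int p = 0; p + seed_k <= rlen; ++p) {
          if (!kmer_code(q, p, seed_k, 5, &code)) continue;
          KmerIndex::const_iterator it = idx.find(code);
          if (it == idx.end()) continue;
          for (size_t z = 0; z < it->second.size(); ++z) {
            int packed = it->second[z];
            int g = packed >> 18, sp = packed & 0x3FFFF;
            int b = (sp - p + rlen) / bucket; // diag shifted non-negative
            votes[((uint64_t)g << 20) | (uint64_t)b]++;
          }
        }
        // best diagonal bucket per gene, then top genes by votes
        std::unordered_map<int, Cand> per_gene;
        for (std::unordered_map<uint64_t, int>::const_iterator it =
               votes.begin(); it != votes.end(); ++it) {
          int g = (int)(it->first >> 20);
          int b = (int)(it->first & 0xFFFFF);
          int diag = b * bucket - rlen;
          std::unordered_map<int, Cand>::iterator pg = per_gene.find(g);
          if (pg == per_gene.end()) {
            Cand c; c.gene = g; c.diag = diag; c.votes = it->second;
            per_gene.insert(std::make_pair(g, c));
          } else if (it->second > pg->second.votes ||
                     (it->second == pg->second.votes &&
                      diag < pg->second.diag)) {
            pg->second.diag = diag; pg->second.votes = it->second;
          }
        }
        for (std::unordered_map<int, Cand>::const_iterator it =
               per_gene.begin(); it != per_gene.end(); ++it)
          cand.push_back(it->second);
        std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
          if (a.votes != b.votes) return a.votes > b.votes;
          return a.gene < b.gene;
        });
        if ((int)cand.size() > max_cand) cand.resize(max_cand);
      }
      for (size_t c = 0; c < cand.size(); ++c) {
        const int g = cand[c].gene;
        const int glen = (int)G[g].size();
        AlnStats a;
        int off = 0;
        if (cand[c].diag < 0 && exact) {
          a = sw_full(q, G[g], sm, gap_open, gap_extend);
        } else {
          int ws = cand[c].diag - margin;
          int we = cand[c].diag + bucket + rlen + margin;
          if (ws < 0) ws = 0;
          if (we > glen) we = glen;
          if (we <= ws) continue;
          std::vector<int> win(G[g].begin() + ws, G[g].begin() + we);
          a = sw_full(q, win, sm, gap_open, gap_extend);
          off = ws;
        }
        if (a.score <= 0 || a.pairs == 0) continue;
        a.sstart += off; a.send += off;
        double ident = 100.0 * a.matches / a.pairs;
        double qcov = (double)(a.qend - a.qstart + 1) / rlen;
        if (ident < min_id || qcov < min_cov) continue;
        bool better = false;
        if (ident > best_id) better = true;
        else if (ident == best_id && a.cols > best_cols) better = true;
        else if (ident == best_id && a.cols == best_cols &&
                 (best_gene < 0 || g < best_gene)) better = true;
        if (better) {
          best_id = ident; best_gene = g; best_cols = a.cols;
          best_strand = strand; best = a;
        }
      }
    }
    if (best_gene >= 0) {
      r_read.push_back(r + 1); r_gene.push_back(best_gene + 1);
      r_ident.push_back(best_id); r_alnlen.push_back(best.cols);
      r_sstart.push_back(best.sstart + 1); r_send.push_back(best.send + 1);
      r_qcov.push_back((double)(best.qend - best.qstart + 1) / (double)rlen);
      r_strand.push_back(best_strand);
    }
  }
  return DataFrame::create(_["read"] = r_read, _["gene"] = r_gene,
    _["identity"] = r_ident, _["aln_len"] = r_alnlen,
    _["sstart"] = r_sstart, _["send"] = r_send,
    _["qcov"] = r_qcov, _["strand"] = r_strand);
}
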