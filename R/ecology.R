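#' Delineate ecotypes from ANI subclades and depth distributions
#'
#' Operationalizes "ecotypes = genomic similarity plus congruent depth
#' zonation": (1) the average-linkage ANI tree over population genomes is cut
#' at \code{cut_ani} percent (default 80) to obtain subclades; (2) each
#' population's depth profile is scaled to [0, 1] (multiple dates per depth
#' are averaged first) and profiles are averaged within subclades; (3)
#' subclades adjacent in peak-depth order are merged while the Pearson
#' correlation of their mean profiles is at least \code{merge_corr}
#' (default 0.8), most-correlated pair first. The resulting groups are the
#' ecotypes, labeled E1, E2, ... from the shallowest peak (peak = argmax
#' over the depth grid, ties to the shallowest depth).
#'
#' @param tree result of \code{\link{order_genomes_by_ani}} on the
#'   population-level ANI matrix (or an \code{hclust} object on
#'   \code{100 - ANI}).
#' @param profiles a \code{coverage_profile} (populations x samples) whose
#'   samples carry depths (via the \code{"samples"} attribute or numeric
#'   column names in meters).
#' @param cut_ani percent ANI at which subclades are read off the tree.
#' @param merge_corr minimum profile correlation for merging subclades into
#'   one ecotype.
#' @return list of class \code{ecotype_model}: \code{map} (population_id,
#'   subclade_id, ecotype_id, peak_depth_m), \code{profiles} (ecotype mean
#'   scaled profiles x depth), \code{subclade_profiles}, \code{congruence}
#'   (correlations of merged pairs), \code{depths}.
#' @export
delineate_ecotypes <- function(tree, profiles, cut_ani = 80,
                               merge_corr = 0.8) {
  hc <- if (inherits(tree, "hclust")) tree else tree$hclust
  if (is.null(hc)) { # single population
    ids <- rownames(profiles)
    sc <- setNames(rep("SC1", length(ids)), ids)
  } else {
    cl <- cutree(hc, h = 100 - cut_ani)
    sc <- setNames(paste0("SC", cl), names(cl))
  }
  missing <- setdiff(names(sc), rownames(profiles))
  if (length(missing) > 0)
    stop("tree leaf without a depth profile: ",
         paste(missing, collapse = ", "))
  depth_prof <- profile_by_depth(profiles)
  depths <- as.numeric(colnames(depth_prof))
  scaled <- scale_profiles(depth_prof)
  # mean scaled profile per subclade
  groups <- split(names(sc), sc)
  sub_prof <- t(vapply(groups, function(g)
    colMeans(scaled[g, , drop = FALSE]), numeric(length(depths))))
  colnames(sub_prof) <- colnames(depth_prof)
  # iterative adjacent-peak merging
  members <- as.list(names(groups))
  repeat {
    prof <- t(vapply(members, function(g)
      colMeans(sub_prof[g, , drop = FALSE]), numeric(length(depths))))
    peaks <- depths[apply(prof, 1, which.max)]
    ord <- order(peaks)
    if (length(members) < 2) break
    cors <- vapply(seq_len(length(ord) - 1), function(i)
      profile_cor(prof[ord[i], ], prof[ord[i + 1], ]), numeric(1))
    if (max(cors) < merge_corr) break
    i <- which.max(cors)
    a <- ord[i]; b <- ord[i + 1]
    members[[a]] <- c(members[[a]], members[[b]])
    members <- members[-b]
  }
  prof <- t(vapply(members, function(g)
    colMeans(sub_prof[g, , drop = FALSE]), numeric(length(depths))))
  colnames(prof) <- colnames(depth_prof)
  peaks <- depths[apply(prof, 1, which.max)]
  ord <- order(peaks)
  members <- members[ord]; prof <- prof[ord, , drop = FALSE]
  peaks <- peaks[ord]
  eco_ids <- paste0("E", seq_along(members))
  rownames(prof) <- eco_ids
  eco_of_sc <- setNames(rep(eco_ids, lengths(members)), unlist(members))
  peak_of_sc <- setNames(rep(peaks, lengths(members)), unlist(members))
  map <- data.frame(population_id = names(sc),
                    subclade_id = unname(sc),
                    ecotype_id = unname(eco_of_sc[sc]),
                    peak_depth_m = unname(peak_of_sc[sc]),
                    stringsAsFactors = FALSE)
  congruence <- vapply(members, function(g) {
    if (length(g) < 2) return(NA_real_)
    p <- sub_prof[g, , drop = FALSE]
    cs <- utils::combn(nrow(p), 2)
    min(vapply(seq_len(ncol(cs)), function(k)
      profile_cor(p[cs[1, k], ], p[cs[2, k], ]), numeric(1)))
  }, numeric(1))
  structure(list(map = map, profiles = prof, subclade_profiles = sub_prof,
                 congruence = setNames(congruence, eco_ids),
                 depths = depths),
            class = "ecotype_model")
}

# Pearson correlation with degenerate-profile guard: constant profiles
# correlate 1 with an identical profile, else 0.
profile_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  cor(a, b)
}

# Average a coverage profile's columns by depth (multiple dates per depth
# collapse to their mean). Columns are renamed to the depth in meters.
profile_by_depth <- function(profiles) {
  meta <- attr(profiles, "samples")
  m <- unclass(profiles)
  depths <- if (!is.null(meta)) meta$depth_m else
    suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(depths))
    stop("profiles need sample depths (metadata or numeric column names)")
  counts <- as.vector(table(depths)) # rowsum rows align with sorted depths
  agg <- t(rowsum(t(m), depths) / counts)
  agg[, order(as.numeric(colnames(agg))), drop = FALSE]
}

#' Pathway-level depth/time profiles
#'
#' A pathway's value in a sample is the mean coverage of its member
#' orthogroups; rows are then scaled to [0, 1] per pathway. The annotation
#' is many-to-many (an orthogroup may feed several pathways); annotations
#' for unknown genes are skipped with a warning.
#'
#' @param og_profile a \code{coverage_profile} (orthogroups x samples).
#' @param annotation data.frame (gene_id, pathway).
#' @param og_table orthogroup membership (orthogroup_id, gene_id) used to
#'   lift gene annotations to orthogroups.
#' @return list of class \code{pathway_profiles}: \code{profiles} (pathways
#'   x samples, scaled), \code{members} (pathway -> orthogroup ids).
#' @export
pathway_profiles <- function(og_profile, annotation, og_table) {
  stopifnot(all(c("gene_id", "pathway") %in% names(annotation)))
  known <- annotation$gene_id %in% og_table$gene_id
  if (!all(known)) {
    warning(sum(!known), " annotation rows reference unknown genes; skipped")
    annotation <- annotation[known, , drop = FALSE]
  }
  if (nrow(annotation) == 0) stop("annotation covers no known gene")
  og_of <- setNames(og_table$orthogroup_id, og_table$gene_id)
  ann <- unique(data.frame(orthogroup_id = og_of[annotation$gene_id],
                           pathway = annotation$pathway,
                           stringsAsFactors = FALSE))
  pws <- sort(unique(ann$pathway))
  m <- t(vapply(pws, function(p) {
    ogs <- intersect(ann$orthogroup_id[ann$pathway == p],
                     rownames(og_profile))
    colMeans(unclass(og_profile)[ogs, , drop = FALSE])
  }, numeric(ncol(og_profile))))
  rownames(m) <- pws
  colnames(m) <- colnames(og_profile)
  structure(list(profiles = scale_profiles(m),
                 members = split(ann$orthogroup_id, ann$pathway),
                 samples = attr(og_profile, "samples")),
            class = "pathway_profiles")
}

#' Hierarchical clustering of pathway depth profiles
#'
#' Ward linkage on Euclidean distances between scaled depth profiles
#' (columns averaged by depth first). The tree is cut at \code{k} clusters
#' or height \code{h}; cluster labels are ordered by mean peak depth,
#' shallowest first.
#'
#' @param pathways a \code{pathway_profiles} object (or a scaled matrix
#'   pathways x depth).
#' @param k number of clusters (or NULL).
#' @param h cut height (used when k is NULL).
#' @return list: \code{clusters} (data.frame pathway, cluster),
#'   \code{hclust}, \code{profiles} (depth-averaged scaled matrix).
#' @export
cluster_pathway_profiles <- function(pathways, k = NULL, h = NULL) {
  m <- if (inherits(pathways, "pathway_profiles")) {
    p <- structure(pathways$profiles, samples = pathways$samples,
                   class = c("coverage_profile", "matrix", "array"))
    profile_by_depth(p)
  } else as.matrix(pathways)
  if (nrow(m) < 2) stop("need at least two pathways")
  hc <- hclust(stats::dist(m), method = "ward.D2")
  cl <- if (!is.null(k)) cutree(hc, k = k)
  else if (!is.null(h)) cutree(hc, h = h)
  else cutree(hc, k = min(3, nrow(m)))
  depths <- as.numeric(colnames(m))
  peak <- depths[apply(m, 1, which.max)]
  mean_peak <- tapply(peak, cl, mean)
  relabel <- setNames(rank(mean_peak, ties.method = "first"),
                      names(mean_peak))
  cl2 <- as.integer(relabel[as.character(cl)])
  list(clusters = data.frame(pathway = rownames(m), cluster = cl2,
                             stringsAsFactors = FALSE),
       hclust = hc, profiles = m)
}
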