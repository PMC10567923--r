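#' ROI atlas for the stress-response network
#'
#' Constructs the 21-ROI atlas of the stress-related network: nine bilateral
#' structures (amygdala, hypothalamus, caudate, putamen, anterior/medial/
#' posterior hippocampus, anterior/posterior insula) plus three midline
#' cortical regions (posterior cingulate, dorsal anterior cingulate, and
#' ventromedial prefrontal cortex). Bilateral pairing maps the 21 ROIs onto
#' 12 anatomical regions; all unordered ROI pairs form the 210-edge list, and
#' every edge carries one of four subnetwork labels used to aggregate
#' connectivity trajectories.
#'
#' Midline ROIs are ordered first so that, under the canonical upper-triangle
#' edge ordering (the first ROI of each pair is the dependent variable of its
#' edge model), every anatomical *region* has at least one dependent-role
#' model: the single ROI that is never dependent is the last bilateral ROI,
#' whose region is covered by its contralateral partner.
#'
#' @param subnetworks Optional edge-level subnetwork assignment: a data frame
#'   with columns `roi_a`, `roi_b`, `subnetwork` covering all edges. By
#'   default a deterministic map derived from anatomical groupings is used;
#'   see [assign_subnetworks()] for a data-driven alternative.
#' @return An object of class `roi_atlas`: a list with tibbles `rois`
#'   (`roi`, `hemisphere`, `region`) and `edges` (`edge_id`, `roi_a`,
#'   `roi_b`, `subnetwork`).
#' @examples
#' atlas <- stress_atlas()
#' nrow(atlas$edges) # 210
#' @export
stress_atlas <- function(subnetworks = NULL) {
  midline <- tibble::tibble(
    roi = c("PCC", "dACC", "vmPFC"),
    hemisphere = "M",
    region = c("PCC", "dACC", "vmPFC")
  )
  bilateral_regions <- c(
    "amygdala", "hypothalamus", "caudate", "putamen",
    "hippocampus_ant", "hippocampus_med", "hippocampus_post",
    "insula_ant", "insula_post"
  )
  bilateral <- tibble::tibble(
    roi = paste0(rep(bilateral_regions, each = 2), c("_L", "_R")),
    hemisphere = rep(c("L", "R"), times = length(bilateral_regions)),
    region = rep(bilateral_regions, each = 2)
  )
  roi_atlas(dplyr::bind_rows(midline, bilateral), subnetworks = subnetworks)
}

#' Build an atlas from an ROI table
#'
#' Generic constructor used both for the full stress network and for small
#' synthetic atlases in simulation studies. Edges are all unordered ROI pairs
#' in canonical (upper-triangle) order.
#'
#' @param rois Data frame with columns `roi`, `hemisphere` (`"L"`, `"R"`, or
#'   `"M"` for midline), `region`. Bilateral regions must have exactly one
#'   `L` and one `R` member.
#' @param subnetworks Optional edge subnetwork table (`roi_a`, `roi_b`,
#'   `subnetwork`); defaults to a deterministic anatomical grouping into
#'   (up to) four subnetworks.
#' @param n_subnetworks Number of subnetworks for the default map.
#' @return A `roi_atlas` object.
#' @export
roi_atlas <- function(rois, subnetworks = NULL, n_subnetworks = 4L) {
  rois <- tibble::as_tibble(rois)
  abort_if(!all(c("roi", "hemisphere", "region") %in% names(rois)),
           "`rois` needs columns roi, hemisphere, region")
  abort_if(anyDuplicated(rois$roi) > 0, "duplicated ROI labels")
  abort_if(nrow(rois) < 2, "an atlas needs at least 2 ROIs")
  bad <- rois |>
    dplyr::filter(.data$hemisphere != "M") |>
    dplyr::count(.data$region, .data$hemisphere) |>
    dplyr::filter(.data$n != 1L)
  abort_if(nrow(bad) > 0, "bilateral regions must have exactly one L and one R ROI")

  n <- nrow(rois)
  idx <- utils::combn(n, 2)
  edges <- tibble::tibble(
    edge_id = seq_len(ncol(idx)),
    roi_a = rois$roi[idx[1, ]],
    roi_b = rois$roi[idx[2, ]]
  )
  if (is.null(subnetworks)) {
    edges$subnetwork <- default_subnetworks(rois, edges, n_subnetworks)
  } else {
    subnetworks <- tibble::as_tibble(subnetworks)
    key <- paste(edges$roi_a, edges$roi_b)
    skey <- paste(subnetworks$roi_a, subnetworks$roi_b)
    pos <- match(key, skey)
    abort_if(anyNA(pos), "`subnetworks` must cover every edge (canonical roi_a < roi_b order)")
    edges$subnetwork <- as.integer(subnetworks$subnetwork[pos])
  }
  abort_if(anyNA(edges$subnetwork), "missing subnetwork assignment")
  structure(list(rois = rois, edges = edges), class = "roi_atlas")
}

# Deterministic subnetwork map: ROIs are grouped into anatomical classes
# (striatal, limbic-subcortical, hippocampal, cortical/insular); an edge is
# assigned the class of its first ROI unless both ROIs share a class.
default_subnetworks <- function(rois, edges, k = 4L) {
  classes <- c(
    amygdala = 2L, hypothalamus = 2L, caudate = 1L, putamen = 1L,
    hippocampus_ant = 3L, hippocampus_med = 3L, hippocampus_post = 3L,
    insula_ant = 4L, insula_post = 4L, PCC = 4L, dACC = 4L, vmPFC = 4L
  )
  cls <- classes[rois$region]
  if (anyNA(cls)) {
    # synthetic atlas with arbitrary region names: cycle regions over groups
    cls <- (match(rois$region, unique(rois$region)) - 1L) %% k + 1L
  }
  names(cls) <- rois$roi
  ca <- cls[edges$roi_a]
  cb <- cls[edges$roi_b]
  as.integer(ifelse(ca == cb, ca, pmin(ca, cb)))
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf(
    "<roi_atlas> %d ROIs, %d regions, %d edges, %d subnetworks\n",
    nrow(x$rois), dplyr::n_distinct(x$rois$region), nrow(x$edges),
    dplyr::n_distinct(x$edges$subnetwork)
  ))
  invisible(x)
}

#' Small synthetic atlas for simulation studies
#'
#' @param n_roi Even number of ROIs >= 4; the first two are midline, the rest
#'   form bilateral pairs.
#' @return A `roi_atlas`.
#' @export
toy_atlas <- function(n_roi = 6L) {
  abort_if(!is_count(n_roi, 4) || n_roi %% 2 != 0,
           "`n_roi` must be an even count >= 4")
  n_pairs <- (n_roi - 2L) / 2L
  rois <- dplyr::bind_rows(
    tibble::tibble(roi = c("mid1", "mid2"), hemisphere = "M",
                   region = c("mid1", "mid2")),
    tibble::tibble(
      roi = paste0(rep(paste0("reg", seq_len(n_pairs)), each = 2), c("_L", "_R")),
      hemisphere = rep(c("L", "R"), n_pairs),
      region = rep(paste0("reg", seq_len(n_pairs)), each = 2)
    )
  )
  roi_atlas(rois)
}

#' Data-driven subnetwork assignment by spectral clustering
#'
#' Groups edges into `k` subnetworks by clustering their group-mean
#' connectivity trajectories: edges with similar mean coupling time courses
#' land in one subnetwork. Provided for synthetic atlases where no published
#' subnetwork map exists; the result is deterministic given `seed`.
#'
#' @param edge_trajectories Matrix or data frame, one row per edge (in atlas
#'   edge order), columns = timepoints of the group-mean coupling.
#' @param k Number of subnetworks.
#' @param seed Seed for k-means initialization.
#' @return Integer vector of subnetwork labels, one per edge.
#' @export
assign_subnetworks <- function(edge_trajectories, k = 4L, seed = 1L) {
  X <- as.matrix(edge_trajectories)
  abort_if(nrow(X) < k, "fewer edges than subnetworks")
  # similarity graph on edge trajectories, normalized Laplacian embedding
  S <- exp(-as.matrix(stats::dist(X))^2 / stats::median(stats::dist(X))^2)
  d <- rowSums(S)
  L <- diag(1 / sqrt(d)) %*% S %*% diag(1 / sqrt(d))
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  with_seed(seed, stats::kmeans(U, centers = k, nstart = 10L)$cluster)
}
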