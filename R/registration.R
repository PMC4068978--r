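# Geometric core: optimal rigid superposition of paired points (Kabsch),
# nearest-neighbour correspondence, trimmed iterative closest point, and
# multi-view merging. This is the surface/surface matching machinery the
# cast-measurement pipeline is built on.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the mean
#' squared distance between `R source_i + t` and `target_i` over the
#' row-paired correspondences. The solution is the classical SVD
#' construction on the centred cross-covariance; a reflection (negative
#' determinant) is corrected by flipping the sign of the smallest singular
#' direction, so the result is always a rotation.
#'
#' @param source,target N x 3 matrices (mm) with row `i` of `source`
#'   corresponding to row `i` of `target`. `N >= 3` and the points must not
#'   be collinear.
#' @return A [rigid_transform()].
#' @export
kabsch <- function(source, target) {
  source <- as_point_matrix(source, "source")
  target <- as_point_matrix(target, "target")
  cm_assert(nrow(source) == nrow(target),
            "source and target must be row-paired (equal N)", "config_error")
  if (nrow(source) < 3L)
    cm_stop("at least 3 point pairs are required for a rigid fit",
            "degeneracy_error")
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2L, cs)
  Tm <- sweep(target, 2L, ct)
  H <- crossprod(S, Tm)
  sv <- svd(H)
  # rank < 2 means the correspondence constrains no unique rotation
  # (coincident or collinear configurations)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12)
    cm_stop("degenerate point configuration: rank-deficient cross-covariance (collinear or coincident points)",
            "degeneracy_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Nearest reference point for each query point
#'
#' Exact 1-nearest-neighbour search by Euclidean distance, backed by a k-d
#' tree. Ties are broken toward the lowest reference row index.
#'
#' @param reference M x 3 matrix of reference points (mm), non-empty.
#' @param queries N x 3 matrix of query points (mm).
#' @return List with `index` (1-based row into `reference`) and
#'   `distance` (mm), each of length N.
#' @export
nearest_neighbors <- function(reference, queries) {
  reference <- as_point_matrix(reference, "reference")
  queries <- as_point_matrix(queries, "queries")
  if (nrow(reference) < 1L)
    cm_stop("reference cloud is empty", "config_error")
  .nn_search_cpp(reference, queries)
}

#' ICP parameters
#'
#' @param max_iterations Iteration cap (default 100).
#' @param rel_rms_tol Convergence threshold on the relative change of the
#'   trimmed RMS between iterations (default 1e-8).
#' @param trim_fraction Fraction of the worst-distance correspondences
#'   discarded each iteration, in `[0, 0.5)` (default 0.1). Robustifies the
#'   fit against points with no true counterpart (e.g. gingival margins).
#' @param min_points Minimum cloud size accepted (default 10).
#' @return List of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, rel_rms_tol = 1e-8,
                       trim_fraction = 0.1, min_points = 10L) {
  cm_assert(max_iterations >= 1, "max_iterations must be >= 1", "config_error")
  cm_assert(rel_rms_tol >= 0, "rel_rms_tol must be >= 0", "config_error")
  cm_assert(trim_fraction >= 0 && trim_fraction < 0.5,
            "trim_fraction must lie in [0, 0.5)", "config_error")
  cm_assert(min_points >= 3, "min_points must be >= 3", "config_error")
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_rms_tol = rel_rms_tol,
                 trim_fraction = trim_fraction,
                 min_points = as.integer(min_points)),
            class = "icp_params")
}

#' Trimmed iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence from the transformed source
#' to the target, rejection of the `trim_fraction` worst-distance pairs,
#' and a Kabsch fit on the survivors, until the trimmed RMS stops changing
#' (relative change below `rel_rms_tol`) or `max_iterations` is reached.
#' The trimmed RMS is non-increasing across iterations.
#'
#' @param source,target Point clouds (N x 3, mm), each with at least
#'   `params$min_points` rows.
#' @param init Initial [rigid_transform()] applied to `source`; defaults to
#'   the identity.
#' @param params An [icp_params()] object.
#' @return List with `transform` (maps `source` into the `target` frame),
#'   `rms` (final trimmed RMS, mm), `iterations`, and `rms_trace` (the
#'   trimmed RMS at each iteration).
#' @export
icp <- function(source, target, init = rigid_transform(), params = icp_params()) {
  source <- as_point_matrix(source, "source")
  target <- as_point_matrix(target, "target")
  cm_assert(inherits(params, "icp_params"), "params must be icp_params()",
            "config_error")
  if (nrow(source) < params$min_points || nrow(target) < params$min_points)
    cm_stop(sprintf("both clouds need >= %d points", params$min_points),
            "degeneracy_error")
  tf <- init
  n <- nrow(source)
  n_keep <- n - floor(params$trim_fraction * n)
  trace <- numeric(0)
  prev <- Inf
  rms <- Inf
  for (it in seq_len(params$max_iterations)) {
    moved <- apply_transform(source, tf)
    nn <- nearest_neighbors(target, moved)
    keep <- order(nn$distance)[seq_len(n_keep)]
    rms <- sqrt(mean(nn$distance[keep]^2))
    trace <- c(trace, rms)
    if (is.finite(prev) &&
        (prev - rms) <= params$rel_rms_tol * max(prev, .Machine$double.xmin))
      break
    prev <- rms
    tf <- kabsch(source[keep, , drop = FALSE],
                 target[nn$index[keep], , drop = FALSE])
  }
  list(transform = tf, rms = rms, iterations = length(trace), rms_trace = trace)
}

#' Merge multiple scanner views into one point cloud
#'
#' Each view is mapped into the common frame by its transform and then,
#' when `refine = TRUE` and previous views exist, refined by ICP against
#' the union of the views merged so far (emulating the registration of a
#' multi-angle cast scan into a single cloud).
#'
#' @param views List of point clouds (N x 3, mm).
#' @param view_transforms List of [rigid_transform()] of the same length.
#' @param refine Run an ICP refinement of each view against the merged
#'   predecessors (default TRUE).
#' @param params [icp_params()] for the refinement.
#' @return Single point matrix with the concatenated, aligned views.
#' @export
merge_views <- function(views, view_transforms, refine = TRUE,
                        params = icp_params()) {
  cm_assert(is.list(views) && is.list(view_transforms),
            "views and view_transforms must be lists", "config_error")
  if (length(views) != length(view_transforms) || length(views) < 1L)
    cm_stop("views and view_transforms must have equal length >= 1",
            "config_error")
  merged <- NULL
  for (i in seq_along(views)) {
    v <- apply_transform(views[[i]], view_transforms[[i]])
    if (refine && !is.null(merged) && nrow(v) >= params$min_points &&
        nrow(merged) >= params$min_points) {
      fit <- icp(v, merged, params = params)
      v <- apply_transform(v, fit$transform)
    }
    merged <- rbind(merged, v)
  }
  merged
}
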