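#' Extract carotenoid band triplets from cohort calls
#'
#' @param calls An `scrs_calls` object (see [classify_cohort()]) or a data
#'   frame with columns `cell_id`, `v1`, `v2`, `v3`.
#' @return Data frame of one `(v1, v2, v3)` triplet per carotenoid-called
#'   cell.
#' @export
carotenoid_triplets <- function(calls) {
  df <- if (inherits(calls, "scrs_calls")) calls$calls else calls
  if (!is.null(df$label)) df <- df[df$label == "carotenoid", , drop = FALSE]
  df <- df[, c("cell_id", "v1", "v2", "v3")]
  if (any(is.na(unlist(df[, c("v1", "v2", "v3")]))))
    stop("triplets contain missing band positions", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Cluster carotenoid cells into types by band-position triplets
#'
#' At ~1 cm^-1 spectral resolution, shifts in the positions of the v1, v2
#' and v3 resonance bands indicate structurally different carotenoids. Two
#' cells share a carotenoid type when they are connected by a chain of
#' triplets whose Chebyshev distance `max(|dv1|, |dv2|, |dv3|)` never
#' exceeds `tol_cm1` (single-linkage agglomeration; `"complete"` linkage is
#' available for users worried about chaining). Type indices are ordered by
#' ascending centroid v3, then v2, then v1, so the labelling is independent
#' of input order.
#'
#' @param triplets Data frame from [carotenoid_triplets()] (columns
#'   `cell_id`, `v1`, `v2`, `v3`).
#' @param tol_cm1 Position tolerance in cm^-1 (default 2, twice the
#'   instrument resolution, absorbing +/-1-point peak jitter).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return An object of class `scrs_types`: `assignment` (cell_id, type),
#'   `centroids` (mean triplet and size per type) and `n_types`.
#' @examples
#' ref <- sorted_samples_reference()
#' tys <- cluster_types(ref$meta[, c("cell_id", "v1", "v2", "v3")])
#' count_types(tys)  # 5
#' @export
cluster_types <- function(triplets, tol_cm1 = 2,
                          linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.finite(tol_cm1) || tol_cm1 < 0)
    stop("`tol_cm1` must be >= 0", call. = FALSE)
  n <- nrow(triplets)
  empty <- data.frame(cell_id = character(), type = integer())
  if (n == 0)
    return(structure(list(assignment = empty,
                          centroids = data.frame(type = integer(),
                                                 v1 = numeric(), v2 = numeric(),
                                                 v3 = numeric(), n = integer()),
                          n_types = 0L, tol_cm1 = tol_cm1, linkage = linkage),
                     class = "scrs_types"))
  m <- as.matrix(triplets[, c("v1", "v2", "v3")])
  if (n == 1) {
    grp <- 1L
  } else {
    d <- stats::dist(m, method = "maximum")
    hc <- stats::hclust(d, method = linkage)
    # cut just above tol so pairs at exactly d == tol share a type
    grp <- stats::cutree(hc, h = tol_cm1 + 1e-9)
  }
  cent <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix)
    data.frame(v1 = mean(m[ix, 1]), v2 = mean(m[ix, 2]), v3 = mean(m[ix, 3]),
               n = length(ix))))
  ord <- order(cent$v3, cent$v2, cent$v1)
  relabel <- integer(nrow(cent))
  relabel[ord] <- seq_along(ord)
  assignment <- data.frame(cell_id = triplets$cell_id,
                           type = relabel[grp], stringsAsFactors = FALSE)
  centroids <- cent[ord, , drop = FALSE]
  centroids <- cbind(type = seq_along(ord), centroids)
  rownames(centroids) <- NULL
  structure(list(assignment = assignment, centroids = centroids,
                 n_types = nrow(centroids), tol_cm1 = tol_cm1,
                 linkage = linkage),
            class = "scrs_types")
}

#' @param assignment An `scrs_types` object.
#' @rdname cluster_types
#' @return `count_types()` returns the number of distinct types.
#' @export
count_types <- function(assignment) {
  stopifnot(inherits(assignment, "scrs_types"))
  assignment$n_types
}

#' @export
print.scrs_types <- function(x, ...) {
  cat(sprintf("<scrs_types> %d cells in %d carotenoid type(s) (tol %g cm^-1, %s linkage)\n",
              nrow(x$assignment), x$n_types, x$tol_cm1, x$linkage))
  if (x$n_types > 0) print(x$centroids, row.names = FALSE)
  invisible(x)
}
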