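# Local Outlier Factor: k-distance, reachability distance, local reachability
# density and LOF, with k-sweeps, dataset reference curves, percentile ranks
# and histogram summaries for distortion features.
#
# Conventions (the original LOF definition):
#   * N_k(p) is the set of all points q != p with d(p,q) <= k-distance(p);
#     distance ties can make |N_k| > k.
#   * reachability distance rd_k(p,q) = max(d(p,q), k-distance(q)), so exact
#     duplicates of q never contribute 0.
#   * if a point's mean reachability distance is 0 (it sits entirely among
#     duplicates), its lrd is capped at 1e12 instead of dividing by zero.

.LRD_CAP <- 1e12

#' Create a feature dataset for outlier analysis
#'
#' @param features Numeric matrix or data frame (rows = points, columns =
#'   feature dimensions, e.g. ruffling and doming amplitudes).
#' @param ids Unique point identifiers; defaults to row names or `p1..pn`.
#' @param labels Optional data frame of per-point labels (coordination,
#'   function class, planted-outlier status, ...).
#' @param standardize If `TRUE`, z-score each feature column before computing
#'   distances.
#' @return A `feature_dataset`: list with the feature matrix `X` (possibly
#'   standardized), `ids`, `labels`, and the Euclidean distance matrix `D`.
#' @export
feature_dataset <- function(features, ids = NULL, labels = NULL,
                            standardize = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("a feature dataset needs at least 2 points", call. = FALSE)
  if (!all(is.finite(X))) stop("feature values must be finite", call. = FALSE)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(X))) rownames(X) else paste0("p", seq_len(nrow(X)))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("point ids must be unique", call. = FALSE)
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  }
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(ids, ids)
  structure(list(X = X, ids = ids, labels = labels,
                 standardize = standardize, D = D),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature_dataset: %d points, %d features%s\n", nrow(x$X),
              ncol(x$X), if (x$standardize) " (z-scored)" else ""))
  invisible(x)
}

ds_index <- function(dataset, id) {
  i <- match(as.character(id), dataset$ids)
  if (is.na(i)) stop("unknown point id '", id, "'", call. = FALSE)
  i
}

check_k <- function(dataset, k) {
  n <- length(dataset$ids)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1L || k > n - 1L)
    stop("k must be an integer in [1, n-1] = [1, ", n - 1L, "]", call. = FALSE)
  as.integer(k)
}

#' k-distance of a point
#'
#' Distance from point `q` to its k-th nearest other point.
#'
#' @param dataset A `feature_dataset`.
#' @param q Point id.
#' @param k Neighborhood size, integer in `[1, n-1]`.
#' @return Distance (same units as the features).
#' @export
k_distance <- function(dataset, q, k) {
  k <- check_k(dataset, k)
  i <- ds_index(dataset, q)
  unname(sort(dataset$D[i, -i])[k])
}

#' Reachability distance of p from q
#'
#' `max(d(p, q), k_distance(q))`: the distance from `p` to `q`, floored at
#' `q`'s k-distance so that points inside `q`'s neighborhood are all "equally
#' reachable". Note the asymmetry: this is a property of the pair ordered
#' (p, q).
#'
#' @inheritParams k_distance
#' @param p,q Distinct point ids.
#' @return Distance.
#' @export
reachability_distance <- function(dataset, p, q, k) {
  ip <- ds_index(dataset, p); iq <- ds_index(dataset, q)
  if (ip == iq) stop("reachability distance requires p != q", call. = FALSE)
  max(dataset$D[ip, iq], k_distance(dataset, q, k))
}

# n x n matrix whose column p holds the sorted distances from p to the other
# points (row k = k-distance of p). Computed once per dataset for k-sweeps.
sorted_off_distances <- function(dataset) {
  Doff <- dataset$D; diag(Doff) <- Inf
  apply(Doff, 1L, sort)
}

# Internal vectorized engine: k-distances, neighbor mask, lrd and LOF for all
# points at a given k. Returns list(kdist, lrd, lof). `sorted` optionally
# carries the precomputed sorted_off_distances() matrix.
lof_engine <- function(dataset, k, sorted = NULL) {
  k <- check_k(dataset, k)
  D <- dataset$D
  n <- nrow(D)
  Doff <- D; diag(Doff) <- Inf
  kdist <- if (is.null(sorted))
    apply(Doff, 1L, function(row) sort(row, partial = k)[k])
  else sorted[k, ]
  # N_k: all points within the k-distance (ties included), self excluded
  M <- Doff <= matrix(kdist, n, n)           # M[p, q]: q in N_k(p)
  # rd(p, q) = max(D[p, q], kdist[q])
  RD <- pmax(D, matrix(kdist, n, n, byrow = TRUE))
  nsize <- rowSums(M)
  mean_rd <- rowSums(RD * M) / nsize
  lrd <- ifelse(mean_rd > 0, 1 / mean_rd, .LRD_CAP)
  lrd <- pmin(lrd, .LRD_CAP)
  lof <- (M %*% lrd) / nsize / lrd
  list(kdist = kdist, neighbors = M, lrd = as.numeric(lrd),
       lof = as.numeric(lof))
}

#' Local reachability density
#'
#' Inverse of the mean reachability distance of `p` from its k nearest
#' neighbors. Capped at `1e12` when `p` lies entirely among duplicates.
#'
#' @inheritParams k_distance
#' @param p Point id.
#' @return Density (1/distance units).
#' @export
lrd <- function(dataset, p, k) {
  lof_engine(dataset, k)$lrd[ds_index(dataset, p)]
}

#' Local Outlier Factor
#'
#' Mean, over the k nearest neighbors of `p`, of the ratio of the neighbor's
#' local reachability density to `p`'s own. Values near 1 mark inliers; values
#' well above 1 mark points in sparser surroundings than their neighbors.
#'
#' @inheritParams lrd
#' @return LOF score (non-negative).
#' @export
lof <- function(dataset, p, k) {
  lof_engine(dataset, k)$lof[ds_index(dataset, p)]
}

#' LOF of every point at one k
#'
#' @inheritParams k_distance
#' @return Named numeric vector of LOF scores (names = point ids).
#' @export
lof_all <- function(dataset, k) {
  stats::setNames(lof_engine(dataset, k)$lof, dataset$ids)
}

#' LOF versus k for one point
#'
#' Sweeps the neighborhood size and records the LOF at every integer k in
#' `[k_min, k_max]`, together with the maximum and its argmax (smallest k on
#' ties).
#'
#' @inheritParams lrd
#' @param k_min,k_max Sweep range, `1 <= k_min <= k_max <= n-1`.
#' @return A `lof_curve`: list with `k_values`, `lof_values`, `max_lof`,
#'   `argmax_k`.
#' @export
lof_curve <- function(dataset, p, k_min = 2L, k_max = 50L) {
  n <- length(dataset$ids)
  k_max <- min(k_max, n - 1L)
  if (k_min > k_max || k_min < 1L)
    stop("invalid k range [", k_min, ", ", k_max, "]", call. = FALSE)
  i <- ds_index(dataset, p)
  ks <- seq.int(k_min, k_max)
  srt <- sorted_off_distances(dataset)
  vals <- vapply(ks, function(k) lof_engine(dataset, k, sorted = srt)$lof[i],
                 numeric(1))
  structure(list(k_values = ks, lof_values = vals,
                 max_lof = max(vals), argmax_k = ks[which.max(vals)]),
            class = "lof_curve")
}

#' Dataset-wide median and minimum LOF curves
#'
#' Per k, the median and minimum of the LOF over all points -- the reference
#' curves against which an individual point's curve is judged.
#'
#' @inheritParams lof_curve
#' @return A `reference_curves`: list with `k_values`, `median_lof`, `min_lof`.
#' @export
reference_curves <- function(dataset, k_min = 2L, k_max = 50L) {
  n <- length(dataset$ids)
  k_max <- min(k_max, n - 1L)
  if (k_min > k_max || k_min < 1L)
    stop("invalid k range [", k_min, ", ", k_max, "]", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  srt <- sorted_off_distances(dataset)
  med <- numeric(length(ks)); mn <- numeric(length(ks))
  for (j in seq_along(ks)) {
    v <- lof_engine(dataset, ks[j], sorted = srt)$lof
    med[j] <- stats::median(v); mn[j] <- min(v)
  }
  structure(list(k_values = ks, median_lof = med, min_lof = mn),
            class = "reference_curves")
}

#' Max-LOF over a k-sweep for every point
#'
#' @inheritParams lof_curve
#' @return Named numeric vector: for each point, the maximum LOF over the
#'   sweep range.
#' @export
max_lof_all <- function(dataset, k_min = 2L, k_max = 50L) {
  n <- length(dataset$ids)
  k_max <- min(k_max, n - 1L)
  if (k_min > k_max || k_min < 1L)
    stop("invalid k range [", k_min, ", ", k_max, "]", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  srt <- sorted_off_distances(dataset)
  best <- rep(-Inf, n)
  for (k in ks) best <- pmax(best, lof_engine(dataset, k, sorted = srt)$lof)
  stats::setNames(best, dataset$ids)
}

#' Percentile rank (mid-rank convention)
#'
#' `100 * (#below + 0.5 * #equal) / n`. With this convention a value equal to
#' the single element of a population ranks at 50, and for duplicate-free
#' populations the ranks of the minimum and maximum sum to 100.
#'
#' @param value Scalar.
#' @param population Non-empty numeric vector.
#' @return Percent in `[0, 100]`.
#' @export
percentile_rank <- function(value, population) {
  population <- as.numeric(population)
  if (length(population) == 0L) stop("population must be non-empty", call. = FALSE)
  100 * (sum(population < value) + 0.5 * sum(population == value)) /
    length(population)
}

#' Histogram counts with half-open bins
#'
#' Bins are `[lo, hi)` with the last bin closed. Values outside the edge range
#' are ignored; counts therefore sum to the number of in-range values.
#'
#' @param values Numeric vector (at least one value).
#' @param bin_edges Strictly increasing edge vector (length = bins + 1), or
#' @param bin_count Number of equal-width bins over the data range.
#' @return Named integer vector of counts, with attribute `"edges"`.
#' @export
histogram_counts <- function(values, bin_edges = NULL, bin_count = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("need at least one value", call. = FALSE)
  if (is.null(bin_edges)) {
    if (is.null(bin_count)) stop("give bin_edges or bin_count", call. = FALSE)
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    bin_edges <- seq(rng[1], rng[2], length.out = bin_count + 1L)
  }
  if (any(diff(bin_edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  names(counts) <- sprintf("[%g,%g%s", bin_edges[-length(bin_edges)],
                           bin_edges[-1L],
                           c(rep(")", nb - 1L), "]"))
  attr(counts, "edges") <- bin_edges
  counts
}

#' Read a feature TSV into a feature dataset
#'
#' Expects a column `id` plus the named feature columns; any remaining
#' columns are kept as labels.
#'
#' @param path TSV path.
#' @param features Character vector of feature column names.
#' @param standardize Passed to [feature_dataset()].
#' @return A `feature_dataset`.
#' @export
read_feature_tsv <- function(path, features = c("ruf", "dom"),
                             standardize = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("feature TSV must have an 'id' column",
                                 call. = FALSE)
  missing <- setdiff(features, names(df))
  if (length(missing))
    stop("feature column(s) not in TSV: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lab_cols <- setdiff(names(df), c("id", features))
  feature_dataset(df[, features, drop = FALSE], ids = df$id,
                  labels = if (length(lab_cols)) df[, lab_cols, drop = FALSE],
                  standardize = standardize)
}
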