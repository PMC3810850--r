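#' Normalized mutual information between two partitions
#'
#' Compares a delimitation with a ground-truth partition of the same items.
#' From the contingency table with cell proportions \eqn{p_{ij}} and
#' marginals \eqn{p_i, p_j}, the mutual information is
#' \eqn{MI = \sum_{ij} p_{ij} \log(p_{ij}/(p_i p_j))} (natural log, empty
#' cells skipped) and
#' \deqn{NMI = MI / \sqrt{H(a)\,H(b)}}
#' with the geometric-mean normalization of the clustering-ensembles
#' literature; \code{normalization = "arithmetic"} divides by
#' \eqn{(H(a)+H(b))/2} instead, for comparison with tools using that
#' variant.  NMI is 1 iff the partitions are identical up to relabelling
#' and 0 when they are independent.  Group labels are arbitrary: only the
#' induced grouping matters.
#'
#' Degenerate cases: if both partitions are single-group (both entropies
#' zero) they are identical and NMI is 1; if exactly one entropy is zero
#' the partitions differ and NMI is 0.
#'
#' @param a,b Partitions over the identical item set (>= 2 items): named
#'   vectors or factors mapping item to group id.  Items are matched by
#'   name; a mismatch in the item sets is an error listing the difference.
#' @param normalization \code{"geometric"} (default) or
#'   \code{"arithmetic"}.
#' @return A number in [0, 1].
#' @examples
#' truth <- c(a1 = "x", a2 = "x", b1 = "y", b2 = "y")
#' est   <- c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)
#' nmi(truth, est)  # 1: identical up to labels
#' @export
nmi <- function(a, b, normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  a <- .as_partition(a, "a")
  b <- .as_partition(b, "b")
  if (length(a) < 2L)
    stop("partitions must cover at least 2 items")
  extra_a <- setdiff(names(a), names(b))
  extra_b <- setdiff(names(b), names(a))
  if (length(extra_a) || length(extra_b))
    stop("item sets differ; only in a: {",
         paste(utils::head(extra_a, 10L), collapse = ", "),
         "}; only in b: {",
         paste(utils::head(extra_b, 10L), collapse = ", "), "}")
  b <- b[names(a)]

  # canonical relabelling (group id -> first-occurrence rank): identical
  # partitions score exactly 1, and ordering the pair deterministically
  # makes nmi(a, b) and nmi(b, a) bitwise equal
  ac <- match(a, unique(a))
  bc <- match(b, unique(b))
  if (identical(ac, bc)) return(1)
  key_a <- paste(ac, collapse = ",")
  key_b <- paste(bc, collapse = ",")
  if (key_b < key_a) { tmp <- a; a <- b; b <- tmp }

  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  Ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  Hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  denom <- switch(normalization,
                  geometric = sqrt(Ha * Hb),
                  arithmetic = (Ha + Hb) / 2)
  # clamp float noise at the boundaries
  min(max(mi / denom, 0), 1)
}

.as_partition <- function(x, what) {
  if (is.factor(x)) x <- stats::setNames(as.character(x), names(x))
  if (!is.atomic(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("partition `", what, "` must be a named vector (item -> group id)")
  if (anyNA(x))
    stop("partition `", what, "` has NA group ids")
  if (anyDuplicated(names(x)))
    stop("partition `", what, "` has duplicated item names")
  stats::setNames(as.character(x), names(x))
}

#' Read a partition from a two-column TSV file
#'
#' @param file Path to a headerless or headered TSV with columns item label
#'   and group id.  A header line is detected when the first field is
#'   \code{"leaf_label"} or \code{"item"}.
#' @return A named character vector (item -> group id).
#' @export
read_partition <- function(file) {
  if (!file.exists(file))
    stop("partition file not found: ", file)
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(d) < 2L)
    stop("partition file needs 2 tab-separated columns: ", file)
  if (d[1, 1] %in% c("leaf_label", "item")) d <- d[-1, , drop = FALSE]
  stats::setNames(d[[2]], d[[1]])
}

#' Write a partition as a two-column TSV file
#'
#' @param partition Named vector (item -> group id).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, file) {
  partition <- .as_partition(partition, "partition")
  utils::write.table(
    data.frame(leaf_label = names(partition), species_id = unname(partition)),
    file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}
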