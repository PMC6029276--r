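## Pairwise evolutionary distances from the trimmed alignment. Jukes-Cantor
## with pairwise deletion of sites where either row lacks an unambiguous
## base; a saturation cap keeps the matrix finite so taxon placement stays
## well-defined for degenerate inputs.

JC_SATURATION_CAP <- 5.0

#' Jukes-Cantor distance between two aligned rows
#'
#' Comparison is restricted to columns where both rows carry a base in
#' A/C/G/T (pairwise deletion). With mismatch fraction p, the distance is
#' -(3/4) log(1 - (4/3) p); p >= 0.75 is mapped to the saturation cap 5.0.
#'
#' @param row_a,row_b equal-length gapped rows.
#' @param labels optional pair of ids for error messages.
#' @return a non-negative distance.
#' @export
jc_distance <- function(row_a, row_b, labels = c("a", "b")) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  if (length(a) != length(b))
    stop("rows of unequal length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  n <- sum(ok)
  if (n == 0L)
    stop(sprintf("no overlapping ungapped columns between '%s' and '%s'",
                 labels[1], labels[2]), call. = FALSE)
  p <- sum(a[ok] != b[ok]) / n
  if (p >= 0.75) return(JC_SATURATION_CAP)
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param alignment alignment with at least 3 rows.
#' @return a symmetric labelled matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  alignment <- as_alignment(alignment)
  n <- length(alignment)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  m <- aln_matrix(alignment)
  is_base <- m == "A" | m == "C" | m == "G" | m == "T"
  labs <- names(alignment)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- is_base[i, ] & is_base[j, ]
      nn <- sum(ok)
      if (nn == 0L)
        stop(sprintf("no overlapping ungapped columns between '%s' and '%s'",
                     labs[i], labs[j]), call. = FALSE)
      p <- sum(m[i, ok] != m[j, ok]) / nn
      d[i, j] <- d[j, i] <- if (p >= 0.75) JC_SATURATION_CAP else
        -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
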