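#' Tamura-Nei (TN93) evolutionary distance between two aligned sequences
#'
#' Closed-form TN93 distance distinguishing the two transition classes
#' (A<->G within purines, C<->T within pyrimidines) from transversions, with
#' empirical base frequencies. Columns where either sequence carries a gap or
#' an IUPAC ambiguity code are removed pairwise before estimation; base
#' frequencies are the combined frequencies of both sequences over the kept
#' columns. No rate heterogeneity (no gamma correction).
#'
#' When any logarithm argument is non-positive the distance is saturated and
#' undefined: `NA_real_` is returned with a warning, never a number.
#'
#' @param a,b Aligned DNA sequences of equal length (character strings or
#'   `DNAString`s; gaps as `-`).
#' @return The TN93 distance (substitutions per site), or `NA_real_` on
#'   saturation.
#' @export
tn93_distance <- function(a, b) {
  av <- strsplit(toupper(as.character(a)), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(as.character(b)), "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) {
    stop("sequences must have equal aligned length")
  }
  plain <- c("A", "C", "G", "T")
  keep <- av %in% plain & bv %in% plain
  av <- av[keep]
  bv <- bv[keep]
  n <- length(av)
  if (n == 0L) stop("no comparable (unambiguous, ungapped) columns")

  counts <- table(factor(c(av, bv), levels = plain))
  g <- as.numeric(counts) / (2 * n)
  names(g) <- plain
  gR <- g["A"] + g["G"]
  gY <- g["C"] + g["T"]

  pair <- paste0(pmin(av, bv), pmax(av, bv))
  P1 <- mean(pair == "AG")                      # purine transitions
  P2 <- mean(pair == "CT")                      # pyrimidine transitions
  Q <- mean(av != bv) - P1 - P2                 # transversions

  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["T"] * g["C"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["T"] * g["C"] * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0 || any(g == 0)) {
    warning("TN93 distance undefined (saturated or missing base class)")
    return(NA_real_)
  }
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

#' Pairwise TN93 distance matrix
#'
#' @param sequences Named list/character vector of aligned sequences of equal
#'   length.
#' @return A symmetric matrix with zero diagonal (`NA` where saturated).
#' @export
tn93_matrix <- function(sequences) {
  sequences <- vapply(sequences, as.character, character(1))
  n <- length(sequences)
  labels <- names(sequences)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- tn93_distance(sequences[[i]], sequences[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion
#' `Q_ij = (n - 2) d_ij - r_i - r_j` and the standard branch-length and
#' distance updates. Ties in Q are broken by the first (row-major) minimum,
#' making the result deterministic. Negative branch lengths are clamped to
#' zero with the residual shifted to the sister edge, preserving the joined
#' pair's path length. The tree is unrooted (trifurcating root node).
#'
#' @param dist A square symmetric numeric matrix with zero diagonal and
#'   `n >= 3` labelled taxa (dimnames used as tip labels).
#' @return A Newick string (with branch lengths, terminated by `;`).
#' @export
neighbor_joining <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("distance matrix must be square")
  }
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(dist) != 0)) stop("distance matrix must have a zero diagonal")
  if (anyNA(dist)) stop("distance matrix contains undefined distances")
  n <- nrow(dist)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels  # Newick fragment per active node
  d <- dist

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    pick <- arrayInd(which.min(q), dim(q))
    i <- min(pick); j <- max(pick)
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], li, nodes[j], lj)
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    nodes <- c(nodes[others], new_node)
  }

  # final three-way join: closed-form three-point branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
          nodes[1], la, nodes[2], lb, nodes[3], lc)
}
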