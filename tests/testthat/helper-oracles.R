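# Independent oracles used by the property tests. These deliberately share no
# code with the package implementations they check.

# Exhaustive dereplication: double loop over clusters x library records,
# applying the conjunctive |dDa| < max_da AND |dppm| < max_ppm rule plus the
# source filter directly.
brute_force_derep <- function(clusters, library, max_da, max_ppm,
                              source_filter = "any") {
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    for (k in seq_len(nrow(library))) {
      dda <- clusters$consensus_mass[i] - library$monoisotopic_mass[k]
      dppm <- dda / library$monoisotopic_mass[k] * 1e6
      ok <- abs(dda) < max_da && abs(dppm) < max_ppm
      if (ok && source_filter != "any") {
        ok <- tolower(library$biological_source[k]) == tolower(source_filter)
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], compound = library$name[k])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(0), compound = character(0)))
  }
  do.call(rbind, out)
}

# random small compound library (decoupled from the package validator except
# for going through compound_library() to get the indexed class)
random_library <- function(n, mass_range = c(100, 1000)) {
  compound_library(data.frame(
    name = sprintf("cmp%04d", seq_len(n)),
    formula = NA_character_,
    monoisotopic_mass = stats::runif(n, mass_range[1], mass_range[2]),
    biological_source = sample(c("Streptomyces", "Rhodococcus", "Nocardia"),
                               n, replace = TRUE),
    activities = sample(c("", "antioxidant", "antibiotic;antifungal"),
                        n, replace = TRUE)
  ), provenance = "random test library")
}

# Exhaustive ends-free (overlap) alignment score by enumerating every
# alignment path; gap runs cost open + len * ext unless they start at the
# first column or end at the last column of the alignment. Only usable for
# very short sequences.
enum_overlap_score <- function(a, b, match = 2, mismatch = -1, open = 5,
                               ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, run_type, run_len, run_from_start) {
    if (i == n && j == m) {
      # a terminal gap run is free
      if (run_type != "D" && !run_from_start) {
        score <- score + open + ext * run_len  # refund the paid cost
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i < n && j < m) {
      s <- if (av[i + 1] == bv[j + 1]) match else mismatch
      rec(i + 1, j + 1, score + s, "D", 0L, FALSE)
    }
    if (i < n) { # gap in b, consume a
      new_run <- run_type != "U"
      from_start <- if (new_run) (i == 0 && j == 0) else run_from_start
      cost <- if (from_start) 0 else if (new_run) open + ext else ext
      rec(i + 1, j, score - cost, "U", if (new_run) 1L else run_len + 1L,
          from_start)
    }
    if (j < m) { # gap in a, consume b
      new_run <- run_type != "L"
      from_start <- if (new_run) (i == 0 && j == 0) else run_from_start
      cost <- if (from_start) 0 else if (new_run) open + ext else ext
      rec(i, j + 1, score - cost, "L", if (new_run) 1L else run_len + 1L,
          from_start)
    }
  }
  rec(0L, 0L, 0, "D", 0L, FALSE)
  best
}

# Rand index between two partitions given as label vectors over the same items
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

# Jukes-Cantor distance from a raw mismatch proportion
jc_distance <- function(p) -3 / 4 * log(1 - 4 * p / 3)

# deterministic sequence pair with equal base composition whose differences
# split 1:1:4 across the two transition classes and the transversions --
# the regime where TN93 collapses to the Jukes-Cantor closed form
balanced_jc_pair <- function(L = 1440, n_diff = 72) {
  per_base <- L / 4
  a <- rep(c("A", "C", "G", "T"), each = per_base)
  b <- a
  k <- n_diff / 12  # 12 symmetric edit slots keep both compositions equal
  flip <- function(from, to, m, offset = 0) {
    i <- which(a == from)[offset + seq_len(m)]
    b[i] <<- to
  }
  flip("A", "G", k)          # purine transitions
  flip("G", "A", k)
  flip("C", "T", k)          # pyrimidine transitions
  flip("T", "C", k)
  flip("A", "C", 2 * k, k)   # transversions, composition-balanced in pairs
  flip("C", "A", 2 * k, k)
  flip("G", "T", 2 * k, k)
  flip("T", "G", 2 * k, k)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       p = n_diff / L)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
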