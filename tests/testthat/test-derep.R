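fixture_clusters <- function(masses, rts = rep(5, length(masses))) {
  data.frame(cluster_id = seq_along(masses), consensus_mass = masses,
             consensus_rt = rts)
}

test_that("the conjunctive tolerance rule is enforced on both dimensions", {
  lib <- baikal_reference_library()
  params <- derep_params(source_filter = "Streptomyces")

  hit <- dereplicate(fixture_clusters(600.3486), lib, params)
  expect_equal(hit$compound[hit$rank == 1], "desferrioxamine E")
  expect_lt(abs(hit$delta_da[1]), 0.001)
  expect_lt(abs(hit$delta_ppm[1]), 10)

  # a §-style unknown: nothing in the library within tolerance
  expect_equal(nrow(dereplicate(fixture_clusters(572.3175), lib, params)), 0)

  # Da passes (0.0008 < 0.001) but ppm fails (16 > 10): rejected
  small <- compound_library(data.frame(
    name = "tiny", formula = NA_character_, monoisotopic_mass = 50.0008,
    biological_source = "Streptomyces", activities = ""))
  expect_equal(nrow(dereplicate(fixture_clusters(50.0000), small,
                                derep_params())), 0)
})

test_that("bounds are strict: boundary-equal differences are rejected", {
  set.seed(21)
  for (rep in 1:40) {
    ref <- runif(1, 100, 900)
    lib <- compound_library(data.frame(
      name = "x", formula = NA_character_, monoisotopic_mass = ref,
      biological_source = "Streptomyces", activities = ""))
    # probe just inside/outside each bound (the other bound kept slack)
    ppm_bound_da <- 10e-6 * ref
    da_bound <- 0.001
    eps <- 1e-7
    probes <- c(ppm_in = ppm_bound_da - eps, ppm_out = ppm_bound_da + eps,
                da_in = da_bound - eps, da_out = da_bound + eps)
    for (nm in names(probes)) {
      p <- if (startsWith(nm, "ppm")) {
        derep_params(max_delta_da = 1, max_delta_ppm = 10)
      } else {
        derep_params(max_delta_da = 0.001, max_delta_ppm = 1e6)
      }
      n <- nrow(dereplicate(fixture_clusters(ref + probes[[nm]]), lib, p))
      expect_equal(n, if (endsWith(nm, "in")) 1L else 0L,
                   info = sprintf("probe %s at ref %.4f", nm, ref))
    }
  }
})

test_that("dereplication equals the brute-force matcher on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    lib <- random_library(40)
    # cluster masses near library masses so matches actually occur
    base <- sample(lib$monoisotopic_mass, 15, replace = TRUE)
    masses <- base + rnorm(15, 0, 0.002)
    clusters <- fixture_clusters(masses)
    src <- sample(c("any", "Streptomyces", "Rhodococcus"), 1)
    params <- derep_params(source_filter = src)
    got <- dereplicate(clusters, lib, params)
    want <- brute_force_derep(clusters, lib, 0.001, 10, src)
    expect_setequal(paste(got$cluster_id, got$compound),
                    paste(want$cluster_id, want$compound))
  }
})

test_that("enlarging either tolerance never removes a match", {
  set.seed(41)
  for (rep in 1:20) {
    lib <- random_library(60)
    clusters <- fixture_clusters(
      sample(lib$monoisotopic_mass, 20, replace = TRUE) + rnorm(20, 0, 0.003))
    tight <- dereplicate(clusters, lib, derep_params(0.001, 10))
    for (p in list(derep_params(0.002, 10), derep_params(0.001, 20),
                   derep_params(0.01, 100))) {
      loose <- dereplicate(clusters, lib, p)
      expect_true(all(paste(tight$cluster_id, tight$compound) %in%
                        paste(loose$cluster_id, loose$compound)))
    }
  }
})

test_that("multiple hits are ranked by absolute ppm error", {
  lib <- compound_library(data.frame(
    name = c("near", "nearer"), formula = NA_character_,
    monoisotopic_mass = c(400.0006, 400.0002),
    biological_source = "Streptomyces", activities = ""))
  res <- dereplicate(fixture_clusters(400.0000), lib, derep_params())
  expect_equal(res$compound, c("nearer", "near"))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("identification summary reproduces the 1-identified / 88-unknown composition", {
  lib <- baikal_reference_library()
  set.seed(51)
  # 89 clusters: 88 at masses far from every Rhodococcus library record,
  # one at the indene-propanoic-acid mass
  decoy_masses <- runif(88, 160, 900)
  repeat {
    near <- apply(abs(outer(decoy_masses, lib$monoisotopic_mass, "-")) < 0.02,
                  1, any)
    if (!any(near)) break
    decoy_masses[near] <- runif(sum(near), 160, 900)
  }
  clusters <- fixture_clusters(c(294.181, decoy_masses))
  res <- dereplicate(clusters, lib, derep_params(source_filter = "Rhodococcus"))
  summ <- summarize_identification(res, clusters)
  expect_equal(summ$identified, 1)
  expect_equal(summ$unknown, 88)
  expect_equal(summ$total, 89)
  expect_equal(unname(summ$activity_counts[["antifungal"]]), 1)

  empty <- summarize_identification(
    dereplicate(fixture_clusters(numeric(0)), lib),
    fixture_clusters(numeric(0)))
  expect_equal(unlist(empty[c("identified", "unknown", "total")]),
               c(identified = 0, unknown = 0, total = 0))
})

test_that("raw m/z matching across the adduct set finds protonated ions", {
  lib <- baikal_reference_library()
  mz <- adduct_mz(600.348277, "[M+H]+")
  res <- dereplicate(fixture_clusters(mz), lib,
                     derep_params(source_filter = "Streptomyces"),
                     mz_mode = TRUE)
  expect_true("desferrioxamine E" %in% res$compound)
  expect_equal(res$adduct[res$compound == "desferrioxamine E"], "[M+H]+")
})
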