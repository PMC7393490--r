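test_that("reference generation is deterministic with guaranteed homopolymers", {
  d <- tempfile(); dir.create(d)
  p1 <- file.path(d, "a.fa"); p2 <- file.path(d, "b.fa")
  r1 <- make_reference(10000, seed = 5, path = p1)
  r2 <- make_reference(10000, seed = 5, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  s <- ref_seq(r1, "chr1", 1, 10000)
  expect_equal(nchar(s), 10000L)
  expect_true(grepl("A{6}|C{6}|G{6}|T{6}", s))
  # a different seed gives a different sequence
  r3 <- make_reference(10000, seed = 6)
  expect_false(identical(s, ref_seq(r3, "chr1", 1, 10000)))
})

test_that("truth sets honor counts, exact stratum allocation and normalization", {
  ref <- make_reference(60000, seed = 2)
  truth <- make_truth(ref, n_snv = 100, n_indel = 40,
                      vaf_strata = c("0.05" = 0.5, "0.25" = 0.5), seed = 3)
  expect_equal(sum(truth$vclass == "SNV"), 100L)
  expect_equal(sum(truth$vclass == "INDEL"), 40L)
  # deterministic allocation: exactly half of each class per stratum
  expect_equal(unname(table(truth$true_vaf[truth$vclass == "SNV"])),
               c(50L, 50L), ignore_attr = TRUE)
  expect_equal(unname(table(truth$true_vaf[truth$vclass == "INDEL"])),
               c(20L, 20L), ignore_attr = TRUE)
  expect_false(anyDuplicated(truth$pos) > 0)
  # every emitted key is already left-aligned and trimmed
  renorm <- normalize_variants(truth[, c("contig", "pos", "ref", "alt")], ref)
  expect_equal(renorm$pos, truth$pos)
  expect_equal(renorm$ref, truth$ref)
  expect_equal(renorm$alt, truth$alt)
})

test_that("single-stratum truth assigns the stated VAF to every variant", {
  ref <- make_reference(30000, seed = 4)
  truth <- make_truth(ref, n_snv = 100, n_indel = 0,
                      vaf_strata = c("0.25" = 1), seed = 5)
  expect_equal(nrow(truth), 100L)
  expect_true(all(truth$true_vaf == 0.25))
})

test_that("infeasible variant density is a hard error", {
  ref <- make_reference(1200, seed = 1)
  expect_error(make_truth(ref, n_snv = 5000, n_indel = 0, seed = 1),
               "infeasible")
})

test_that("perfect callers reproduce the truth exactly through the whole pipeline", {
  d <- tempfile(); dir.create(d)
  ref <- make_reference(30000, seed = 21, path = file.path(d, "ref.fa"))
  truth <- make_truth(ref, n_snv = 80, n_indel = 20, seed = 22)
  profiles <- lapply(c("LoFreq", "MuTect2", "Strelka", "VarDict"), function(ca) {
    caller_profile(ca, sens_midpoint = 0, sens_slope = 1e6, sens_max = 1,
                   fp_rate = 0, vaf_noise_sd = 0)
  })
  vcfs <- make_caller_vcfs(truth, profiles, ref, d, seed = 23)
  for (x in vcfs) {
    expect_equal(nrow(x$table), nrow(truth))
  }
  callsets <- lapply(names(vcfs), function(ca) {
    read_caller_vcf(vcfs[[ca]]$path, ca, ref = ref)
  })
  tab <- decide_all(merge_callsets(callsets, voting_preset("deep")))
  expect_true(all(tab$decision == "PASS"))
  r <- compare_calls(tab[, c("contig", "pos", "ref", "alt")], truth)
  expect_equal(c(r$recall, r$precision, r$f1), c(1, 1, 1))
})

test_that("simulated VCFs are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_ensemble(d1, contig_length = 20000, n_snv = 50, n_indel = 10,
                          seed = 33)
  s2 <- simulate_ensemble(d2, contig_length = 20000, n_snv = 50, n_indel = 10,
                          seed = 33)
  for (f in c("reference.fa", "truth.vcf", "truth.tsv", "LoFreq.vcf",
              "MuTect2.vcf", "Strelka.vcf", "VarDict.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("consensus recall at k of n matches the binomial tail", {
  # four callers with constant sensitivity 0.8 and no false positives:
  # a variant passes a 2-of-4 vote with P(X >= 2), X ~ Bin(4, 0.8)
  d <- tempfile(); dir.create(d)
  ref <- make_reference(90000, seed = 41, path = file.path(d, "ref.fa"))
  truth <- make_truth(ref, n_snv = 1000, n_indel = 0,
                      vaf_strata = c("0.25" = 1), seed = 42)
  profiles <- lapply(c("LoFreq", "MuTect2", "Strelka", "VarDict"), function(ca) {
    caller_profile(ca, sens_midpoint = -1, sens_slope = 100, sens_max = 0.8,
                   fp_rate = 0, vaf_noise_sd = 0)
  })
  vcfs <- make_caller_vcfs(truth, profiles, ref, d, seed = 43)
  callsets <- lapply(names(vcfs), function(ca) {
    read_caller_vcf(vcfs[[ca]]$path, ca, ref = ref)
  })
  cfg <- voting_config(c("LoFreq", "MuTect2", "Strelka", "VarDict"))
  tab <- decide_all(merge_callsets(callsets, cfg))
  pass <- tab[tab$decision == "PASS", c("contig", "pos", "ref", "alt")]
  r <- compare_calls(pass, truth)
  expected <- 1 - pbinom(1, 4, 0.8)      # 0.9728
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(r$recall - expected), 3 * se)
  expect_equal(r$precision, 1)
})

test_that("per-caller detection rates track the logistic sensitivity curve", {
  d <- tempfile(); dir.create(d)
  ref <- make_reference(90000, seed = 51, path = file.path(d, "ref.fa"))
  truth <- make_truth(ref, n_snv = 1000, n_indel = 0,
                      vaf_strata = c("0.01" = 0.5, "0.25" = 0.5), seed = 52)
  pr <- caller_profile("MuTect2", sens_midpoint = 0.05, sens_slope = 100,
                       sens_max = 0.9, fp_rate = 0, vaf_noise_sd = 0)
  vcfs <- make_caller_vcfs(truth, list(pr), ref, d, seed = 53)
  tab <- vcfs$MuTect2$table
  for (v in c(0.01, 0.25)) {
    n_v <- sum(truth$true_vaf == v)
    n_det <- sum(tab$true_vaf == v, na.rm = TRUE)
    p <- detection_prob(pr, v)
    expect_lt(abs(n_det / n_v - p), 4 * sqrt(p * (1 - p) / n_v) + 1e-9)
  }
})

test_that("the adaptive scheme rescues low-VAF SNVs that majority voting loses", {
  # the mechanism behind the low-VAF claim: one caller (MuTect2) remains
  # sensitive below 3% VAF while the rest are blind there, so only the
  # adaptive rule can keep those variants
  d <- tempfile(); dir.create(d)
  ref <- make_reference(90000, seed = 61, path = file.path(d, "ref.fa"))
  truth <- make_truth(ref, n_snv = 600, n_indel = 0,
                      vaf_strata = c("0.01" = 0.4, "0.02" = 0.3, "0.1" = 0.3),
                      seed = 62)
  profiles <- list(
    caller_profile("MuTect2", sens_midpoint = 0.002, sens_slope = 2000,
                   sens_max = 0.95, fp_rate = 10, vaf_noise_sd = 0.002),
    caller_profile("Strelka", sens_midpoint = 0.06, sens_slope = 150,
                   sens_max = 0.95, fp_rate = 10, vaf_noise_sd = 0.002),
    caller_profile("LoFreq", sens_midpoint = 0.06, sens_slope = 150,
                   sens_max = 0.9, fp_rate = 10, vaf_noise_sd = 0.002),
    caller_profile("VarDict", sens_midpoint = 0.08, sens_slope = 150,
                   sens_max = 0.9, fp_rate = 10, vaf_noise_sd = 0.002))
  vcfs <- make_caller_vcfs(truth, profiles, ref, d, seed = 63)
  callsets <- lapply(names(vcfs), function(ca) {
    read_caller_vcf(vcfs[[ca]]$path, ca, ref = ref)
  })
  callers <- c("LoFreq", "MuTect2", "Strelka", "VarDict")
  adaptive <- decide_all(merge_callsets(callsets, voting_preset("deep")))
  majority <- decide_all(merge_callsets(callsets,
                                        voting_config(callers)))
  low_truth <- truth[truth$true_vaf < 0.03, ]
  n_low <- function(tab) {
    pass <- tab[tab$decision == "PASS", c("contig", "pos", "ref", "alt")]
    compare_calls(pass, low_truth)$tp
  }
  expect_gt(n_low(adaptive), n_low(majority))
  # the rescue must not collapse precision: allow at most 0.15 below majority
  prec <- function(tab) {
    pass <- tab[tab$decision == "PASS", c("contig", "pos", "ref", "alt")]
    compare_calls(pass, truth)$precision
  }
  expect_gt(prec(adaptive), prec(majority) - 0.15)
})
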