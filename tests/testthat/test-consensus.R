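deep_cfg <- voting_preset("deep")

test_that("majority voting rounds the fractional cutoff up", {
  expect_true(majority_vote(2, 4, 0.5))    # 2 of 4 at 50%
  expect_false(majority_vote(1, 4, 0.5))
  expect_false(majority_vote(3, 7, 0.5))   # 50% of 7 means >= 4
  expect_true(majority_vote(4, 7, 0.5))
  expect_false(majority_vote(0, 4, 0.5))
  # absolute count mode
  expect_true(majority_vote(2, 7, min_callers = 2))
  expect_false(majority_vote(1, 7, min_callers = 2))
  # no spurious ceiling from float representation (0.1 * 30 is exactly 3)
  expect_true(majority_vote(3, 30, 0.1))
})

test_that("the adaptive rules fire in order on their printed conditions", {
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), 0.05, deep_cfg, 4)
  expect_true(v$pass); expect_equal(v$rule, 1L)
  v <- vaf_adaptive_vote("MuTect2", 0.01, deep_cfg, 4)
  expect_true(v$pass); expect_equal(v$rule, 2L)
  v <- vaf_adaptive_vote("LoFreq", 0.20, deep_cfg, 4)
  expect_false(v$pass); expect_true(is.na(v$rule))
  # boundary grid of rule 1: >= 0.03 and <= 0.1 are inclusive
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), 0.03, deep_cfg, 4)
  expect_equal(v$rule, 1L)
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), 0.1, deep_cfg, 4)
  expect_equal(v$rule, 1L)
  # 0.029 misses rule 1 but passes rule 2 (MuTect2 supports) — recorded as 2;
  # it would also pass rule 3 with 2 of 4
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), 0.029, deep_cfg, 4)
  expect_true(v$pass); expect_equal(v$rule, 2L)
  # 0.101 falls back to the majority rule
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), 0.101, deep_cfg, 4)
  expect_true(v$pass); expect_equal(v$rule, 3L)
  # a missing VAF disables rules 1-2 only
  v <- vaf_adaptive_vote(c("Strelka", "MuTect2"), NA, deep_cfg, 4)
  expect_equal(v$rule, 3L)
  v <- vaf_adaptive_vote("MuTect2", NA, deep_cfg, 4)
  expect_false(v$pass)
})

test_that("both voting schemes agree with literal re-encodings of the printed rules", {
  callers7 <- SUPPORTED_CALLERS
  for (n in c(3, 4, 7)) {
    set <- callers7[seq_len(n)]
    set <- union(c("Strelka", "MuTect2"), set)[seq_len(n)]
    cfg <- voting_config(snv_callers = set, snv_scheme = "vaf_adaptive")
    for (support in support_patterns(set)) {
      for (vaf in vaf_grid) {
        got <- vaf_adaptive_vote(support, vaf, cfg, n)
        expect_equal(got$pass, oracle_adaptive(support, vaf, n))
        expect_equal(majority_vote(length(support), n),
                     oracle_majority(length(support), n))
      }
    }
  }
})

test_that("the reported VAF follows caller priority and skips missing values", {
  pr <- deep_cfg$priority
  expect_equal(select_reported_vaf(c(Strelka = 0.12, LoFreq = 0.10), pr), 0.12)
  expect_equal(select_reported_vaf(c(LoFreq = 0.07), pr), 0.07)
  expect_equal(select_reported_vaf(c(MuTect2 = NA, Strelka = 0.2), pr), 0.2)
  expect_true(is.na(select_reported_vaf(c(MuTect2 = NA, LoFreq = NA), pr)))
})

test_that("merging builds the union with exact per-variant support", {
  k1 <- variant_key("chr1", 100, "A", "T")
  k2 <- variant_key("chr1", 200, "C", "G")
  k3 <- variant_key("chr2", 50, "G", "A")
  a <- as_callset("MuTect2", rbind(k1, k2), tumor_vaf = c(0.1, 0.2))
  b <- as_callset("Strelka", rbind(k2, k3), tumor_vaf = c(0.25, 0.3))
  tab <- merge_callsets(list(a, b), deep_cfg)
  expect_equal(nrow(tab), 3L)
  ks <- key_string(tab$contig, tab$pos, tab$ref, tab$alt)
  expect_equal(tab$callers[[which(ks == "chr1:200:C:G")]],
               c("MuTect2", "Strelka"))
  expect_equal(tab$n_support[ks == "chr1:200:C:G"], 2L)

  # identical single-variant sets from two callers dedup to one row
  tab2 <- merge_callsets(list(as_callset("MuTect2", k1, 0.1),
                              as_callset("Strelka", k1, 0.1)), deep_cfg)
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$n_support, 2L)
})

test_that("merging validates its inputs", {
  k <- variant_key("chr1", 1, "A", "T")
  cs <- as_callset("MuTect2", k, 0.1)
  expect_error(merge_callsets(list(cs), deep_cfg), "two or more")
  expect_error(merge_callsets(list(cs, as_callset("MuTect2", k, 0.2)),
                              deep_cfg), "duplicate")
  expect_error(merge_callsets(list(cs, as_callset("MuSE", k, 0.2)), deep_cfg),
               "not in the voting configuration")
})

test_that("merge agrees with a brute-force set-algebra oracle on random callsets", {
  set.seed(99)
  keys <- random_keys(1000)
  callers <- c("LoFreq", "MuTect2", "Strelka", "VarDict")
  membership <- matrix(runif(nrow(keys) * 4) < 0.5, ncol = 4,
                       dimnames = list(NULL, callers))
  membership[rowSums(membership) == 0, 1] <- TRUE
  callsets <- lapply(callers, function(ca) {
    as_callset(ca, keys[membership[, ca], , drop = FALSE], tumor_vaf = 0.2)
  })
  tab <- merge_callsets(callsets, deep_cfg)
  expect_equal(nrow(tab), nrow(keys))
  ks_tab <- key_string(tab$contig, tab$pos, tab$ref, tab$alt)
  ks_in <- key_string(keys$contig, keys$pos, keys$ref, keys$alt)
  expect_setequal(ks_tab, ks_in)
  m <- match(ks_in, ks_tab)
  for (i in seq_len(nrow(keys))) {
    expect_identical(sort(tab$callers[[m[i]]]), sort(callers[membership[i, ]]))
  }
  # re-merging the table's own support reproduces it exactly
  callsets2 <- lapply(callers, function(ca) {
    sel <- vapply(tab$callers, function(s) ca %in% s, TRUE)
    as_callset(ca, tab[sel, c("contig", "pos", "ref", "alt")], tumor_vaf = 0.2)
  })
  tab2 <- merge_callsets(callsets2, deep_cfg)
  expect_equal(tab2[, c("contig", "pos", "ref", "alt", "n_support")],
               tab[, c("contig", "pos", "ref", "alt", "n_support")])
})

test_that("decisions combine confidence, rules and the minimum-VAF demotion", {
  k1 <- variant_key("chr1", 100, "A", "T")  # 3 of 4, high VAF -> CONSENSUS
  k2 <- variant_key("chr1", 200, "C", "G")  # MuTect2 only, VAF 0.02 -> LOWVAF
  mk <- function(cfg) {
    decide_all(merge_callsets(list(
      as_callset("MuTect2", rbind(k1, k2), tumor_vaf = c(0.3, 0.02)),
      as_callset("Strelka", k1, 0.3),
      as_callset("LoFreq", k1, 0.3)), cfg))
  }
  tab <- mk(deep_cfg)
  expect_equal(tab$confidence[tab$pos == 100], "CONSENSUS")
  expect_equal(tab$vote_rule[tab$pos == 100], 3L)
  expect_equal(tab$confidence[tab$pos == 200], "LOWVAF")
  expect_equal(tab$vote_rule[tab$pos == 200], 2L)
  expect_equal(tab$decision, c("PASS", "PASS"))

  # the same inputs under a min-VAF threshold demote the low-VAF rescue
  tab2 <- mk(voting_preset("deep", min_tumor_vaf = 0.05))
  expect_equal(tab2$decision[tab2$pos == 200], "REJECT")
  expect_equal(tab2$reject_reason[tab2$pos == 200], "MIN_VAF")
  expect_equal(tab2$decision[tab2$pos == 100], "PASS")
})

test_that("indels vote by plain majority even under the adaptive preset", {
  k <- variant_key("chr1", 100, "AT", "A")
  # MuTect2 alone at low VAF would pass rule 2 for an SNV; an indel must not
  tab <- decide_all(merge_callsets(list(
    as_callset("MuTect2", k, 0.02),
    as_callset("LoFreq", variant_key("chr1", 500, "G", "C"), 0.4)), deep_cfg))
  expect_equal(tab$decision[tab$vclass == "INDEL"], "REJECT")
})

test_that("per-class caller restriction drops records from non-voting callers", {
  # MuSE is not in the deep preset; its records must not enter the table
  k <- variant_key("chr1", 100, "A", "T")
  tab <- merge_callsets(list(
    as_callset("MuSE", k, 0.2),
    as_callset("MuTect2", variant_key("chr1", 200, "C", "G"), 0.2),
    as_callset("Strelka", variant_key("chr1", 200, "C", "G"), 0.2)),
    voting_preset("wgs"))
  # MuSE votes for SNVs in the wgs preset but not for indels
  expect_equal(nrow(tab), 2L)
  tab2 <- merge_callsets(list(
    as_callset("MuSE", variant_key("chr1", 100, "AT", "A"), 0.2),
    as_callset("MuTect2", variant_key("chr1", 200, "C", "G"), 0.2)),
    voting_preset("wgs"))
  expect_equal(nrow(tab2), 1L)  # the MuSE indel is outside its voting set
})

test_that("adding support never demotes a passing variant (monotonicity)", {
  for (n in c(4, 7)) {
    set <- union(c("Strelka", "MuTect2"), SUPPORTED_CALLERS)[seq_len(n)]
    cfg <- voting_config(snv_callers = set, snv_scheme = "vaf_adaptive")
    for (support in support_patterns(set)) {
      for (vaf in c(0.01, 0.05, 0.2, NA)) {
        base <- vaf_adaptive_vote(support, vaf, cfg, n)$pass
        for (extra in setdiff(set, support)) {
          grown <- vaf_adaptive_vote(c(support, extra), vaf, cfg, n)$pass
          expect_false(base && !grown)
        }
      }
    }
  }
})

test_that("voting configuration rejects invalid settings", {
  expect_error(voting_config(c("MuTect2", "MuTect2")), "duplicate")
  expect_error(voting_config("GATK"), "unknown caller")
  expect_error(voting_config(c("LoFreq", "MuTect2"), cutoff = 0), "fraction")
  expect_error(voting_config(c("LoFreq", "MuTect2"), low_vaf = 0.2,
                             mid_vaf = 0.1), "low_vaf")
  expect_error(voting_config(c("LoFreq", "MuTect2"),
                             snv_scheme = "vaf_adaptive"),
               "anchor")
})
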