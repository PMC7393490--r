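#' Per-caller detection profile for the simulator
#'
#' Describes how a simulated caller behaves: a logistic
#' sensitivity-versus-VAF curve, a genome-wide false-positive rate and
#' Gaussian noise on the reported VAF. The detection probability at true
#' VAF `v` is `sens_max / (1 + exp(-sens_slope * (v - sens_midpoint)))`.
#'
#' @param caller name from [SUPPORTED_CALLERS].
#' @param sens_midpoint VAF at half-maximal detection.
#' @param sens_slope logistic steepness (per unit VAF).
#' @param sens_max plateau sensitivity in `[0, 1]`.
#' @param fp_rate expected false positives per megabase.
#' @param vaf_noise_sd standard deviation of the reported-VAF noise.
#' @return a `caller_profile` object.
#' @export
caller_profile <- function(caller, sens_midpoint = 0.02, sens_slope = 300,
                           sens_max = 0.95, fp_rate = 5, vaf_noise_sd = 0.005) {
  caller <- match_caller(caller)
  stopifnot(sens_max >= 0, sens_max <= 1, fp_rate >= 0, vaf_noise_sd >= 0)
  structure(list(caller = caller, sens_midpoint = sens_midpoint,
                 sens_slope = sens_slope, sens_max = sens_max,
                 fp_rate = fp_rate, vaf_noise_sd = vaf_noise_sd),
            class = "caller_profile")
}

#' @rdname caller_profile
#' @param profile a `caller_profile`.
#' @param vaf numeric vector of true VAFs.
#' @return `detection_prob()`: detection probabilities in `[0, sens_max]`.
#' @export
detection_prob <- function(profile, vaf) {
  profile$sens_max / (1 + exp(-profile$sens_slope * (vaf - profile$sens_midpoint)))
}

# plausible deep-sequencing behavior per caller; MuTect2 is the most
# sensitive at low VAF, VarScan/VarDict need more support
default_profiles <- function(callers) {
  base <- list(
    LoFreq  = list(sens_midpoint = 0.015, sens_slope = 300, sens_max = 0.92, fp_rate = 4),
    MuSE    = list(sens_midpoint = 0.025, sens_slope = 250, sens_max = 0.88, fp_rate = 3),
    MuTect  = list(sens_midpoint = 0.012, sens_slope = 300, sens_max = 0.90, fp_rate = 6),
    MuTect2 = list(sens_midpoint = 0.008, sens_slope = 400, sens_max = 0.96, fp_rate = 5),
    Strelka = list(sens_midpoint = 0.020, sens_slope = 300, sens_max = 0.95, fp_rate = 3),
    VarDict = list(sens_midpoint = 0.030, sens_slope = 200, sens_max = 0.90, fp_rate = 8),
    VarScan = list(sens_midpoint = 0.040, sens_slope = 150, sens_max = 0.85, fp_rate = 10)
  )
  lapply(callers, function(ca) {
    do.call(caller_profile, c(list(caller = ca), base[[match_caller(ca)]]))
  })
}

#' Generate a deterministic random reference contig
#'
#' Pseudo-random DNA with homopolymer runs (one run of at least six
#' identical bases every ~1 kb) inserted to exercise indel
#' left-alignment. The same seed always yields the same sequence.
#'
#' @param length contig length in bases (>= 1000).
#' @param seed integer RNG seed.
#' @param contig contig name.
#' @param path optional FASTA output path; an `.fai` index is written
#'   alongside.
#' @return a [ref_context()]; when `path` is given the file path is
#'   attached as attribute `"path"`.
#' @export
make_reference <- function(length, seed = 1L, contig = "chr1", path = NULL) {
  stopifnot(length >= 1000)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, length, replace = TRUE)
  # one homopolymer run of 6-9 bases per kb, clear of the contig ends
  run_starts <- seq.int(500L, length - 20L, by = 1000L)
  for (s in run_starts) {
    run_len <- sample(6:9, 1L)
    seq[s:(s + run_len - 1L)] <- sample(bases, 1L)
  }
  s <- paste(seq, collapse = "")
  ctx <- ref_context(stats::setNames(s, contig))
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(stats::setNames(s, contig))
    Biostrings::writeXStringSet(dna, path, width = 70L)
    Rsamtools::indexFa(path)
    attr(ctx, "path") <- path
  }
  ctx
}

#' Generate a ground-truth somatic variant set
#'
#' Draws unique, normalized SNVs and indels on a reference contig with a
#' controllable VAF distribution, emulating a dilution series: each
#' stratum is a (VAF, proportion) pair and variants are allocated to
#' strata deterministically (largest-remainder rounding), so stratum
#' sizes are exact and reproducible. The default strata place equal
#' numbers of variants at the expected heterozygous VAFs of a 1-50%
#' tumor dilution series (0.005, 0.01, 0.025, 0.05, 0.1, 0.25).
#'
#' @param ref a [ref_context()] (see [make_reference()]).
#' @param n_snv,n_indel variant counts.
#' @param vaf_strata named numeric vector: `names` are VAF values,
#'   values are proportions summing to 1.
#' @param max_indel_len maximum inserted/deleted length.
#' @param seed integer RNG seed.
#' @param vcf_path,tsv_path optional output paths for the truth VCF and
#'   the (key, true VAF) table.
#' @return data.frame `contig`, `pos`, `ref`, `alt`, `vclass`,
#'   `true_vaf` — every key a fixed point of [normalize_variants()].
#' @export
make_truth <- function(ref, n_snv = 300L, n_indel = 60L,
                       vaf_strata = c("0.005" = 1/6, "0.01" = 1/6,
                                      "0.025" = 1/6, "0.05" = 1/6,
                                      "0.1" = 1/6, "0.25" = 1/6),
                       max_indel_len = 6L, seed = 1L,
                       vcf_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(ref, "ref_context"))
  if (abs(sum(vaf_strata) - 1) > 1e-9) stop("vaf_strata proportions must sum to 1")
  set.seed(seed)
  contig <- names(ref$seqs)[1]
  L <- ref_contig_length(ref, contig)
  n_total <- n_snv + n_indel
  spacing <- max_indel_len + 14L  # > max left shift through a homopolymer run
  grid <- seq.int(spacing + 1L, L - spacing - 1L, by = spacing)
  if (n_total > length(grid)) {
    stop("infeasible density: ", n_total, " variants but only ",
         length(grid), " usable positions on a ", L, " bp contig")
  }
  pos <- sort(sample(grid, n_total))
  is_snv <- rep(c(TRUE, FALSE), c(n_snv, n_indel))[sample.int(n_total)]

  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n_total)
  used <- integer(0)
  for (i in seq_len(n_total)) {
    p <- pos[i]
    for (try in 1:20) {
      rb <- ref_seq(ref, contig, p, p)
      if (is_snv[i]) {
        key <- variant_key(contig, p, rb, sample(setdiff(bases, rb), 1L))
      } else {
        len <- sample.int(max_indel_len, 1L)
        if (stats::runif(1) < 0.5) {  # deletion
          key <- variant_key(contig, p, ref_seq(ref, contig, p, p + len), rb)
        } else {                      # insertion
          ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
          key <- variant_key(contig, p, rb, paste0(rb, ins))
        }
        key$alt_index <- NULL
      }
      key <- normalize_variants(key, ref)
      if (!key$pos %in% used) break
    }
    if (key$pos %in% used) {
      stop("could not place a unique variant near ", contig, ":", p)
    }
    used <- c(used, key$pos)
    rows[[i]] <- key
  }
  truth <- do.call(rbind, rows)
  truth$vclass <- classify_variant(truth$ref, truth$alt)

  # deterministic largest-remainder allocation of strata, per class
  vafs <- as.numeric(names(vaf_strata))
  alloc <- function(n) {
    exact <- vaf_strata * n
    cnt <- floor(exact)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    rep(vafs, cnt)
  }
  truth$true_vaf <- NA_real_
  truth$true_vaf[truth$vclass == "SNV"] <- alloc(sum(truth$vclass == "SNV"))
  truth$true_vaf[truth$vclass == "INDEL"] <- alloc(sum(truth$vclass == "INDEL"))
  truth <- order_keys(truth)
  rownames(truth) <- NULL

  if (!is.null(vcf_path)) write_truth_vcf(truth, contig, L, seed, vcf_path)
  if (!is.null(tsv_path)) {
    utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  truth
}

write_truth_vcf <- function(truth, contig, contig_len, seed, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=vcfensemble simulator",
           sprintf("##simulation_seed=%d", as.integer(seed)),
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"True tumor variant allele fraction\">",
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")))
  body <- paste(truth$contig, truth$pos, ".", truth$ref, truth$alt, ".",
                "PASS", sprintf("VAF=%.6g", truth$true_vaf), sep = "\t")
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

# ---- per-caller VCF emission ------------------------------------------------

#' Simulate per-caller VCFs from a truth set
#'
#' Each true variant is detected by caller `c` independently with
#' probability `detection_prob(profile_c, true VAF)`; a detected
#' variant's reported VAF is the true VAF plus Gaussian noise, clamped
#' into `(0, 1]`. False positives (SNVs with VAFs drawn uniformly from
#' 0.01-0.2) are placed at unused positions at `fp_rate` per megabase.
#' Every file is written in its caller's dialect — Strelka tier counts,
#' VarScan `FREQ` percent strings, LoFreq `INFO AF` with no sample
#' columns, `FORMAT AF/FA/AD` for the rest — so the dialect readers are
#' genuinely exercised. VAFs are quantized by each dialect (e.g. to read
#' counts at the simulated depth); the `vaf_encoded` column of the
#' returned tables gives the value actually written.
#'
#' @param truth a [make_truth()] table.
#' @param profiles list of [caller_profile()]s with distinct callers.
#' @param ref the [ref_context()] the truth was drawn on.
#' @param dir output directory; one `<caller>.vcf` per profile.
#' @param seed integer RNG seed.
#' @param depth simulated tumor read depth (controls VAF quantization).
#' @return invisible list: per caller, `path` and the emitted table
#'   (`contig`, `pos`, `ref`, `alt`, `is_fp`, `true_vaf`,
#'   `vaf_encoded`).
#' @export
make_caller_vcfs <- function(truth, profiles, ref, dir, seed = 1L,
                             depth = 10000L) {
  callers <- vapply(profiles, function(p) p$caller, "")
  if (anyDuplicated(callers)) stop("profiles must cover distinct callers")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  contig <- names(ref$seqs)[1]
  L <- ref_contig_length(ref, contig)
  out <- list()
  for (pr in profiles) {
    detected <- stats::runif(nrow(truth)) < detection_prob(pr, truth$true_vaf)
    tab <- truth[detected, c("contig", "pos", "ref", "alt", "true_vaf"),
                 drop = FALSE]
    tab$is_fp <- rep(FALSE, nrow(tab))
    noisy <- tab$true_vaf +
      stats::rnorm(nrow(tab), 0, pr$vaf_noise_sd)
    tab$vaf_raw <- pmin(pmax(noisy, 1 / depth), 1)

    n_fp <- stats::rpois(1L, pr$fp_rate * L / 1e6)
    if (n_fp > 0) {
      fp_pos <- sample(setdiff(seq.int(20L, L - 20L), truth$pos), n_fp)
      fp <- data.frame(contig = contig, pos = as.integer(fp_pos),
                       stringsAsFactors = FALSE)
      fp$ref <- vapply(fp$pos, function(p) ref_seq(ref, contig, p, p), "")
      fp$alt <- vapply(fp$ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }, "")
      fp$true_vaf <- NA_real_
      fp$is_fp <- TRUE
      fp$vaf_raw <- stats::runif(n_fp, 0.01, 0.2)
      tab <- rbind(tab, fp)
    }
    tab <- order_keys(tab)
    rownames(tab) <- NULL
    path <- file.path(dir, paste0(pr$caller, ".vcf"))
    tab$vaf_encoded <- write_caller_dialect_vcf(tab, pr$caller, contig, L,
                                                seed, path, depth)
    out[[pr$caller]] <- list(path = path,
                             table = tab[, c("contig", "pos", "ref", "alt",
                                             "is_fp", "true_vaf",
                                             "vaf_encoded")])
  }
  invisible(out)
}

#' Write variants in one caller's VCF dialect
#'
#' Low-level emitter used by [make_caller_vcfs()]; exported so tests can
#' construct dialect fixtures directly.
#'
#' @param tab data.frame with `contig`, `pos`, `ref`, `alt`, `vaf_raw`.
#' @param caller name from [SUPPORTED_CALLERS].
#' @param contig,contig_len contig header information.
#' @param seed recorded in the header.
#' @param path output file.
#' @param depth simulated tumor depth used to quantize VAFs into counts.
#' @return numeric vector of the VAF values actually encoded, in `tab`
#'   row order.
#' @export
write_caller_dialect_vcf <- function(tab, caller, contig, contig_len, seed,
                                     path, depth = 10000L) {
  caller <- match_caller(caller)
  n <- nrow(tab)
  v <- tab$vaf_raw
  alt_n <- as.integer(round(v * depth))
  ref_n <- depth - alt_n
  hdr_common <- c("##fileformat=VCFv4.2",
                  sprintf("##source=vcfensemble simulator (%s dialect)", caller),
                  sprintf("##simulation_seed=%d", as.integer(seed)),
                  sprintf("##contig=<ID=%s,length=%d>", contig, contig_len))
  col8 <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  mk_hdr <- function(defs, samples = c("NORMAL", "TUMOR")) {
    cols <- if (is.null(samples)) col8 else c(col8, "FORMAT", samples)
    c(hdr_common, defs, paste0("#", paste(cols, collapse = "\t")))
  }
  fixed <- function(info, format = NULL, normal = NULL, tumor = NULL) {
    row <- paste(tab$contig, tab$pos, ".", tab$ref, tab$alt, "100", "PASS",
                 info, sep = "\t")
    if (!is.null(format)) {
      row <- paste(row, format, normal, tumor, sep = "\t")
    }
    row
  }
  gt_n <- "0/0"; gt_t <- "0/1"
  if (caller == "LoFreq") {
    enc <- round(v, 6)
    hdr <- mk_hdr(c("##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
                    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">"),
                  samples = NULL)
    body <- fixed(sprintf("DP=%d;AF=%.6f", depth, v))
  } else if (caller == "MuTect") {
    enc <- round(v, 6)
    hdr <- mk_hdr(c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    "##FORMAT=<ID=FA,Number=A,Type=Float,Description=\"Allele fraction\">",
                    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"))
    body <- fixed(sprintf("DP=%d", depth), "GT:FA:DP",
                  sprintf("%s:0.000000:%d", gt_n, depth),
                  sprintf("%s:%.6f:%d", gt_t, v, depth))
  } else if (caller %in% c("MuTect2", "VarDict")) {
    enc <- round(v, 6)
    defs <- c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
    if (caller == "VarDict") {
      defs <- c(defs,
                "##FORMAT=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
                "##FORMAT=<ID=NM,Number=1,Type=Float,Description=\"Mean mismatches\">")
      fmt <- "GT:AF:AD:DP:MQ:NM"
      tum <- sprintf("%s:%.6f:%d,%d:%d:60.0:0.0", gt_t, v, ref_n, alt_n, depth)
      nor <- sprintf("%s:0.000000:%d,0:%d:60.0:0.0", gt_n, depth, depth)
    } else {
      fmt <- "GT:AF:AD:DP"
      tum <- sprintf("%s:%.6f:%d,%d:%d", gt_t, v, ref_n, alt_n, depth)
      nor <- sprintf("%s:0.000000:%d,0:%d", gt_n, depth, depth)
    }
    hdr <- mk_hdr(defs)
    body <- fixed(sprintf("DP=%d", depth), fmt, nor, tum)
  } else if (caller == "MuSE") {
    enc <- alt_n / depth
    hdr <- mk_hdr(c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
                    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"))
    body <- fixed(sprintf("SOMATIC"), "GT:AD:DP",
                  sprintf("%s:%d,0:%d", gt_n, depth, depth),
                  sprintf("%s:%d,%d:%d", gt_t, ref_n, alt_n, depth))
    hdr <- c(hdr[1:(length(hdr) - 1)],
             "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic\">",
             hdr[length(hdr)])
  } else if (caller == "VarScan") {
    enc <- round(v * 100, 4) / 100
    hdr <- mk_hdr(c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency\">",
                    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"))
    body <- fixed(sprintf("DP=%d", depth), "GT:FREQ:DP",
                  sprintf("%s:0%%:%d", gt_n, depth),
                  sprintf("%s:%.4f%%:%d", gt_t, v * 100, depth))
  } else if (caller == "Strelka") {
    enc <- alt_n / depth
    is_snv <- nchar(tab$ref) == 1L & nchar(tab$alt) == 1L
    hdr <- mk_hdr(c("##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
                    "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A counts tier1,tier2\">",
                    "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C counts tier1,tier2\">",
                    "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G counts tier1,tier2\">",
                    "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T counts tier1,tier2\">",
                    "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"Reference-supporting reads tier1,tier2\">",
                    "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"Indel-supporting reads tier1,tier2\">"))
    body <- character(n)
    for (i in seq_len(n)) {
      if (is_snv[i]) {
        cnt <- stats::setNames(integer(4), c("A", "C", "G", "T"))
        cnt[tab$ref[i]] <- ref_n[i]
        cnt[tab$alt[i]] <- cnt[tab$alt[i]] + alt_n[i]
        fmt <- "DP:AU:CU:GU:TU"
        pair <- function(x) sprintf("%d,%d", x, x)
        tum <- paste(depth, pair(cnt["A"]), pair(cnt["C"]), pair(cnt["G"]),
                     pair(cnt["T"]), sep = ":")
        ncnt <- stats::setNames(integer(4), c("A", "C", "G", "T"))
        ncnt[tab$ref[i]] <- depth
        nor <- paste(depth, pair(ncnt["A"]), pair(ncnt["C"]), pair(ncnt["G"]),
                     pair(ncnt["T"]), sep = ":")
      } else {
        fmt <- "DP:TAR:TIR"
        tum <- sprintf("%d:%d,%d:%d,%d", depth, ref_n[i], ref_n[i],
                       alt_n[i], alt_n[i])
        nor <- sprintf("%d:%d,%d:0,0", depth, depth, depth)
      }
      body[i] <- paste(tab$contig[i], tab$pos[i], ".", tab$ref[i], tab$alt[i],
                       "100", "PASS", "SOMATIC", fmt, nor, tum, sep = "\t")
    }
    hdr <- c(hdr[1:(length(hdr) - 1)],
             "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic\">",
             hdr[length(hdr)])
  }
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  enc
}

#' Generate a complete synthetic ensemble fixture
#'
#' One call produces everything the pipeline needs: an indexed reference
#' FASTA, a truth VCF and table, and one dialect-faithful VCF per
#' requested caller, all under `dir` and fully determined by `seed`.
#'
#' @param dir output directory (created if needed).
#' @param contig_length reference length in bases.
#' @param n_snv,n_indel,vaf_strata,max_indel_len forwarded to
#'   [make_truth()].
#' @param callers caller names; default the deep-sequencing SNV preset
#'   set.
#' @param profiles optional list of [caller_profile()]s overriding the
#'   defaults for `callers`.
#' @param seed integer RNG seed (recorded in every output header).
#' @param depth simulated tumor depth.
#' @return list with `ref` (context), `truth` (table), `caller_vcfs`
#'   (per-caller paths + emitted tables) and `paths`.
#' @export
simulate_ensemble <- function(dir, contig_length = 100000L, n_snv = 300L,
                              n_indel = 60L,
                              vaf_strata = c("0.005" = 1/6, "0.01" = 1/6,
                                             "0.025" = 1/6, "0.05" = 1/6,
                                             "0.1" = 1/6, "0.25" = 1/6),
                              max_indel_len = 6L,
                              callers = c("LoFreq", "MuTect2", "Strelka",
                                          "VarDict"),
                              profiles = NULL, seed = 1L, depth = 10000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  ref <- make_reference(contig_length, seed = seed, path = fa)
  truth <- make_truth(ref, n_snv = n_snv, n_indel = n_indel,
                      vaf_strata = vaf_strata, max_indel_len = max_indel_len,
                      seed = seed + 1L,
                      vcf_path = file.path(dir, "truth.vcf"),
                      tsv_path = file.path(dir, "truth.tsv"))
  if (is.null(profiles)) profiles <- default_profiles(callers)
  vcfs <- make_caller_vcfs(truth, profiles, ref, dir, seed = seed + 2L,
                           depth = depth)
  list(ref = ref, truth = truth, caller_vcfs = vcfs,
       paths = c(reference = fa, truth_vcf = file.path(dir, "truth.vcf"),
                 truth_tsv = file.path(dir, "truth.tsv"),
                 vapply(vcfs, function(x) x$path, "")))
}
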