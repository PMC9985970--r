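# End-to-end orchestration: which analysis runs for which behavioural
# context, result-table assembly and serialization.
#
# Run matrix: response-phase circular statistics and IOI-ratio analyses run
# in every context (self-referential phases when no partner is calling);
# Granger causality and ADAM fitting run only in the interactive contexts
# (one-way and two-way), where a partner stream exists.

INTERACTIVE_CONTEXTS <- c("one_way", "two_way")

pipeline_log <- function(level, msg, log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[log_level]]) {
    message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    toupper(level), msg))
  }
}

# Focal/partner identities per context, inferred from roles.
context_pairing <- function(calls) {
  focal <- unique(calls$individual_id[calls$role == "focal"])
  partner <- unique(calls$individual_id[calls$role %in% c("partner", "playback")])
  list(focal = focal, partner = partner)
}

phase_sample_for_context <- function(calls, ctx) {
  sub <- segment_bouts(calls[calls$context == ctx, , drop = FALSE],
                          ici_scope = "per_individual")
  pairing <- context_pairing(sub)
  if (ctx %in% INTERACTIVE_CONTEXTS && length(pairing$partner) > 0) {
    phases <- list()
    for (f in pairing$focal) {
      for (p in pairing$partner) {
        ph <- response_phases(sub, f, p)
        if (nrow(ph) > 0) {
          ph$individual_id <- f
          phases[[length(phases) + 1L]] <- ph
        }
      }
    }
    if (length(phases) == 0) return(NULL)
    out <- do.call(rbind, phases)
  } else {
    phases <- list()
    for (ind in unique(sub$individual_id)) {
      own <- sub[sub$individual_id == ind & !is.na(sub$bout_id), , drop = FALSE]
      for (b in unique(own$bout_id)) {
        ph <- self_referential_phases(sort(own$onset_s[own$bout_id == b]))
        if (nrow(ph) > 0) {
          ph$bout_id <- b
          ph$individual_id <- ind
          phases[[length(phases) + 1L]] <- ph
        }
      }
    }
    if (length(phases) == 0) return(NULL)
    out <- do.call(rbind, phases)
  }
  out$context <- ctx
  out
}

#' Run the full analysis pipeline on an annotated dataset
#'
#' Executes, per behavioural context present in the input: bout segmentation,
#' response-phase extraction (self-referential in the non-interactive
#' contexts), the circular test battery, cross-context phase comparisons
#' (presence of a calling partner, type of partner, presence of a silent
#' partner), IOI-ratio categorical rhythm analyses, and — in the interactive
#' contexts only — Granger causality scans and ADAM fits with permutation
#' envelopes. Results are written as tidy CSV files plus a JSON summary; the
#' run is deterministic given `seed`.
#'
#' @param input Path to a canonical-CSV annotation file, or a call
#'   annotation tibble.
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_perm Permutation replicates for the ADAM envelopes and the
#'   two-sample phase comparisons.
#' @param n_boot Bootstrap replicates for the von Mises goodness-of-fit
#'   test.
#' @param n_sim_null Simulated pairs for the null ratio distributions.
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"error"`.
#' @return Invisibly, the summary list (also written to `summary.json`).
#'   Output files: `circular_results.csv`, `ratio_results.csv`,
#'   `granger_results.csv`, `adam_results.json`, `summary.json`.
#' @export
run_pipeline <- function(input, outdir, seed = 1, n_perm = 200,
                         n_boot = 199, n_sim_null = 1e5,
                         log_level = "info") {
  calls <- if (is.character(input)) read_call_annotations(input) else input
  validate_annotations(calls)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  contexts <- intersect(CONTEXTS, unique(calls$context))
  summary <- list(seed = seed, contexts = contexts, blocks = list())
  failed <- FALSE

  run_stage <- function(name, fun) {
    pipeline_log("info", sprintf("stage %s", name), log_level)
    tryCatch(fun(), error = function(e) {
      pipeline_log("error", sprintf("stage %s FAILED: %s", name,
                                    conditionMessage(e)), log_level)
      failed <<- TRUE
      structure(list(error = conditionMessage(e)), class = "vr_stage_failure")
    })
  }

  ## circular statistics per context + cross-context comparisons
  phase_samples <- list()
  circ_rows <- run_stage("circular", function() {
    rows <- list()
    for (ctx in contexts) {
      ph <- phase_sample_for_context(calls, ctx)
      phase_samples[[ctx]] <<- ph
      if (is.null(ph) || nrow(ph) < 8) next
      ang <- ph$angle_deg
      s <- circular_summary(ang)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test_name = "summary", statistic = s$rho, p_value = NA_real_,
        n = s$n, n2 = NA_integer_, mu0 = s$mu, method = "descriptive",
        p_asymptotic = NA_real_, context = ctx, comparison = NA_character_)
      add <- function(row, ctx) { row$context <- ctx
        row$comparison <- NA_character_; row }
      rows[[length(rows) + 1L]] <- add(rayleigh_test(ang), ctx)
      rows[[length(rows) + 1L]] <- add(v_test(ang, 0), ctx)
      rows[[length(rows) + 1L]] <- add(v_test(ang, 90), ctx)
      suite <- uniformity_suite(ang, n_boot = n_boot,
                                seed = derive_seed(seed, paste0("suite_", ctx)))
      suite$context <- ctx
      suite$comparison <- NA_character_
      rows[[length(rows) + 1L]] <- suite
    }
    comparisons <- list(
      c("alone", "one_way"), c("silent_partner", "two_way"),
      c("one_way", "two_way"), c("alone", "silent_partner"))
    for (cmp in comparisons) {
      a <- phase_samples[[cmp[1]]]; b <- phase_samples[[cmp[2]]]
      if (is.null(a) || is.null(b) || nrow(a) < 8 || nrow(b) < 8) next
      row <- watson_two_sample(a$angle_deg, b$angle_deg, n_perm = n_perm,
                               seed = derive_seed(seed, paste(cmp, collapse = "_")))
      row$context <- cmp[1]
      row$comparison <- paste(cmp, collapse = " vs ")
      rows[[length(rows) + 1L]] <- row
    }
    do.call(rbind, rows)
  })

  ## categorical rhythm per context
  ratio_rows <- run_stage("ratios", function() {
    rows <- list()
    binning <- build_sir_bins()
    for (ctx in contexts) {
      sub <- segment_bouts(calls[calls$context == ctx, , drop = FALSE],
                          ici_scope = "per_individual")
      pairing <- context_pairing(sub)
      modes <- if (ctx %in% INTERACTIVE_CONTEXTS) c("own", "pooled") else "own"
      for (f in unique(pairing$focal)) {
        for (mode in modes) {
          br <- compute_bout_ratios(sub, ioi_mode = mode, focal_id = f)
          if (nrow(br) < 10) next
          iois <- unlist(lapply(
            split(sub$onset_s[!is.na(sub$bout_id) &
                                (mode == "pooled" | sub$individual_id == f)],
                  sub$bout_id[!is.na(sub$bout_id) &
                                (mode == "pooled" | sub$individual_id == f)]),
            function(on) diff(sort(on))))
          null <- simulate_null_ratios(iois, n_sim = n_sim_null,
                                       seed = derive_seed(seed, paste0("null_", ctx, mode, f)))
          ks <- ks_against_null(br$ratio, null)
          ks$context <- ctx; ks$individual_id <- f; ks$ioi_mode <- mode
          ks$sir <- NA_character_
          rows[[length(rows) + 1L]] <- ks
          if (ks$p_value < 0.05 && length(unique(br$bout_id)) >= 6) {
            for (sir in binning$bins$label) {
              pk <- sir_peak_test(br, binning, sir)
              pk$context <- ctx; pk$individual_id <- f; pk$ioi_mode <- mode
              pk$degenerate <- NULL
              rows[[length(rows) + 1L]] <- tibble::tibble(
                test_name = pk$test_name, statistic = pk$statistic,
                p_value = pk$p_value, n = pk$n, context = ctx,
                individual_id = f, ioi_mode = mode, sir = sir)
            }
          }
        }
      }
    }
    if (length(rows) == 0) return(tibble::tibble())
    do.call(rbind, rows)
  })

  ## Granger causality: interactive contexts only
  granger_rows <- run_stage("granger", function() {
    rows <- list()
    for (ctx in intersect(contexts, INTERACTIVE_CONTEXTS)) {
      sub <- segment_bouts(calls[calls$context == ctx, , drop = FALSE],
                          ici_scope = "per_individual")
      pairing <- context_pairing(sub)
      dirs <- if (ctx == "one_way") "partner_to_focal" else
        c("partner_to_focal", "focal_to_partner")
      for (f in pairing$focal) {
        for (p in pairing$partner) {
          for (lvl in c("session", "bout")) {
            series_list <- build_paired_series(sub, f, p, level = lvl)
            for (ser in series_list) {
              tab <- granger_scan(ser, directions = dirs)
              tab$context <- ctx; tab$focal_id <- f; tab$partner_id <- p
              rows[[length(rows) + 1L]] <- tab
            }
          }
        }
      }
    }
    if (length(rows) == 0) return(tibble::tibble())
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(out$p_value * sum(!is.na(out$p_value)), 1)
    out
  })

  ## ADAM: interactive contexts only
  adam_results <- run_stage("adam", function() {
    res <- list()
    for (ctx in intersect(contexts, INTERACTIVE_CONTEXTS)) {
      sub <- segment_bouts(calls[calls$context == ctx, , drop = FALSE],
                          ici_scope = "per_individual")
      pairing <- context_pairing(sub)
      for (f in pairing$focal) {
        for (p in pairing$partner) {
          bout_series <- build_paired_series(sub, f, p, level = "bout")
          if (length(bout_series) == 0) next
          series <- concatenate_bouts(bout_series)
          for (version in c("adaptation_only", "joint")) {
            key <- sprintf("%s|%s|%s|%s", ctx, f, p, version)
            fit <- tryCatch({
              pt <- adam_permutation_test(
                series, version, n_perm = max(n_perm, 100),
                seed = derive_seed(seed, key))
              list(
                context = ctx, focal_id = f, partner_id = p, version = version,
                estimates = as.list(pt$fit$estimates),
                sigma_hat = pt$fit$sigma_hat, sse = pt$fit$sse,
                n_terms = pt$fit$n_terms, flags = as.list(pt$fit$flags),
                envelope = pt$envelope, n_perm = pt$n_perm,
                seed = derive_seed(seed, key))
            }, vr_error = function(e) list(
              context = ctx, focal_id = f, partner_id = p, version = version,
              excluded_reason = conditionMessage(e)))
            res[[key]] <- fit
          }
        }
      }
    }
    res
  })

  ## serialize
  write_block <- function(x, file) {
    if (inherits(x, "vr_stage_failure")) {
      writeLines(sprintf("FAILED: %s", x$error), file.path(outdir, paste0(file, ".FAILED")))
      return("failed")
    }
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(outdir, paste0(file, ".csv")),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(x, file.path(outdir, paste0(file, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }
    "ok"
  }
  summary$blocks$circular <- write_block(circ_rows, "circular_results")
  summary$blocks$ratios <- write_block(ratio_rows, "ratio_results")
  summary$blocks$granger <- if (length(intersect(contexts, INTERACTIVE_CONTEXTS)) == 0)
    "not_applicable" else write_block(granger_rows, "granger_results")
  summary$blocks$adam <- if (length(intersect(contexts, INTERACTIVE_CONTEXTS)) == 0)
    "not_applicable" else write_block(adam_results, "adam_results")
  summary$failed <- failed
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (failed) {
    pipeline_log("error", "pipeline finished with failed stages", log_level)
  } else {
    pipeline_log("info", "pipeline finished", log_level)
  }
  invisible(summary)
}
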