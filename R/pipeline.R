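# End-to-end study workflow: simulate -> validity filter -> score ->
# estimate both waves' networks -> centrality -> bootstrap stability ->
# permutation comparison -> cross-lagged network -> summary report.
# Every stage draws its seed deterministically from the master seed, so
# a config fully reproduces all outputs.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master seed; per-stage seeds derive from it via
#'   [child_seed()].
#' @param n_t1,n_t2 Simulated wave-1 sample size and the number also
#'   observed at wave 2.
#' @param rates Quality-control violation rates
#'   ([inject_qc_violations()]).
#' @param qc Validity-filter thresholds ([qc_config()]).
#' @param gamma,path_size Network estimator settings.
#' @param boot_B Edge-bootstrap replicates.
#' @param cs_B Case-drop subsamples per drop level.
#' @param drop_grid Case-drop proportions.
#' @param n_perm Network-comparison permutations (0 skips the stage).
#' @param folds,lambda_rule Cross-lagged network settings.
#' @param cutoffs Named prevalence cutoffs per construct (screening
#'   conventions, e.g. `c(PHQ = 10, GAD = 10)`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("cognet_run_"), seed = 1L,
                       n_t1 = 1000, n_t2 = round(n_t1 / 3),
                       rates = c(lie = 0.03, missing = 0.04, fast = 0.03),
                       qc = qc_config(),
                       gamma = 0.5, path_size = 100,
                       boot_B = 1000, cs_B = 250,
                       drop_grid = seq(0.05, 0.75, by = 0.05),
                       n_perm = 1000, folds = 10, lambda_rule = "min",
                       cutoffs = c(PHQ = 10, GAD = 10)) {
  structure(as.list(environment()), class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

write_network_files <- function(net, prefix, out_dir) {
  write.csv(net$W, file.path(out_dir, paste0(prefix, "_matrix.csv")))
  utils::write.table(edge_list(net),
                     file.path(out_dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_json_file(net$meta, file.path(out_dir, paste0(prefix, "_meta.json")))
}

#' Run the full two-wave network analysis workflow
#'
#' Executes every stage of the study workflow on synthetic data with
#' known ground truth and writes all tabular artifacts (CSV/TSV/JSON)
#' plus a machine-readable `summary.json` and human-readable
#' `summary.md` into `config$out_dir`. Stage timings go to `log.txt`
#' (kept out of the summary so that reruns with one seed are
#' byte-identical). A stage failure aborts with the stage name; outputs
#' of completed stages remain on disk.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of every stage
#'   and `summary` (the summary list).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat("pipeline run, master seed ", config$seed, "\n", sep = "",
      file = log_path)
  res <- list()
  summary <- list(seed = config$seed)
  t_prev <- Sys.time()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    now <- Sys.time()
    cat(sprintf("%-12s %6.2f s\n", name,
                as.numeric(difftime(now, t_prev, units = "secs"))),
        file = log_path, append = TRUE)
    t_prev <<- now
    out
  }

  sim <- stage("simulate", simulate_two_wave_study(
    make_default_truth(config$seed), n_t1 = config$n_t1,
    n_t2 = config$n_t2, seed = config$seed, rates = config$rates))
  res$sim <- sim

  qc1 <- stage("qc_t1", apply_qc(sim$records_t1, config$qc))
  qc2 <- stage("qc_t2", apply_qc(sim$records_t2, config$qc))
  write_json_file(list(
    t1 = qc1$report[c("n_input", "n_retained", "exclusions")],
    t2 = qc2$report[c("n_input", "n_retained", "exclusions")]),
    file.path(config$out_dir, "qc_report.json"))
  res$qc <- list(t1 = qc1, t2 = qc2)
  summary$qc <- list(
    t1 = list(n_input = qc1$report$n_input,
              n_retained = qc1$report$n_retained,
              exclusions = as.list(qc1$report$exclusions)),
    t2 = list(n_input = qc2$report$n_input,
              n_retained = qc2$report$n_retained,
              exclusions = as.list(qc2$report$exclusions)))

  scores <- stage("score", {
    s1 <- score_records(qc1$retained)
    s2 <- score_records(qc2$retained)
    write.csv(rbind(s1, s2), file.path(config$out_dir, "scores.csv"),
              row.names = FALSE)
    list(t1 = s1, t2 = s2)
  })
  matched <- stage("match", match_waves(scores$t1, scores$t2))
  res$scores <- scores
  res$matched <- matched
  summary$matched <- as.list(matched$counts)

  summary$prevalence <- stage("prevalence", {
    out <- list()
    for (lab in names(config$cutoffs)) {
      out[[lab]] <- list(
        cutoff = config$cutoffs[[lab]],
        t1 = prevalence(scores$t1, lab, config$cutoffs[[lab]]),
        t2 = prevalence(scores$t2, lab, config$cutoffs[[lab]]))
    }
    out
  })

  paired_t <- stage("compare_waves", compare_waves(matched))
  write.csv(paired_t, file.path(config$out_dir, "paired_t.csv"),
            row.names = FALSE)
  res$paired_t <- paired_t
  summary$paired_t <- paired_t

  nets <- stage("estimate", {
    n1 <- estimate_network(scores$t1, gamma = config$gamma,
                           path_size = config$path_size)
    n2 <- estimate_network(scores$t2, gamma = config$gamma,
                           path_size = config$path_size)
    write_network_files(n1, "network_t1", config$out_dir)
    write_network_files(n2, "network_t2", config$out_dir)
    list(t1 = n1, t2 = n2)
  })
  res$networks <- nets
  summary$network <- list(
    t1 = list(edges = nets$t1$meta$edges, density = nets$t1$meta$density,
              global_strength = global_strength(nets$t1)),
    t2 = list(edges = nets$t2$meta$edges, density = nets$t2$meta$density,
              global_strength = global_strength(nets$t2)))

  cents <- stage("centrality", {
    c1 <- centrality_table(nets$t1)
    c2 <- centrality_table(nets$t2)
    write.csv(c1, file.path(config$out_dir, "centrality_t1.csv"),
              row.names = FALSE)
    write.csv(c2, file.path(config$out_dir, "centrality_t2.csv"),
              row.names = FALSE)
    list(t1 = c1, t2 = c2)
  })
  res$centrality <- cents
  summary$strength_order <- list(
    t1 = cents$t1$node[order(-cents$t1$strength)],
    t2 = cents$t2$node[order(-cents$t2$strength)])

  boot <- stage("bootstrap", {
    be <- bootstrap_edges(scores$t1, B = config$boot_B,
                          seed = child_seed(config$seed, 11),
                          gamma = config$gamma,
                          path_size = config$path_size)
    write.csv(be$edges, file.path(config$out_dir, "edge_ci_t1.csv"),
              row.names = FALSE)
    cs1 <- case_drop_cs(scores$t1, B = config$cs_B,
                        drop_grid = config$drop_grid,
                        seed = child_seed(config$seed, 12),
                        gamma = config$gamma,
                        path_size = config$path_size)
    cs2 <- case_drop_cs(scores$t2, B = config$cs_B,
                        drop_grid = config$drop_grid,
                        seed = child_seed(config$seed, 13),
                        gamma = config$gamma,
                        path_size = config$path_size)
    write.csv(rbind(cbind(wave = "T1", cs1$curve),
                    cbind(wave = "T2", cs2$curve)),
              file.path(config$out_dir, "cs_curve.csv"),
              row.names = FALSE)
    write_json_file(list(t1 = as.list(cs1$cs), t2 = as.list(cs2$cs)),
                    file.path(config$out_dir, "cs.json"))
    list(edges = be, cs_t1 = cs1, cs_t2 = cs2)
  })
  res$bootstrap <- boot
  summary$cs <- list(t1 = as.list(boot$cs_t1$cs),
                     t2 = as.list(boot$cs_t2$cs))

  if (config$n_perm > 0) {
    cmp <- stage("compare", nct(matched$t1, matched$t2,
                                design = "paired",
                                n_perm = config$n_perm,
                                seed = child_seed(config$seed, 14),
                                gamma = config$gamma,
                                path_size = config$path_size))
    write.csv(cmp$per_edge, file.path(config$out_dir, "nct_edges.csv"),
              row.names = FALSE)
    write_json_file(cmp[c("gs1", "gs2", "gs_diff", "gs_p",
                          "omnibus_stat", "omnibus_p", "n_perm",
                          "design")],
                    file.path(config$out_dir, "nct.json"))
    res$nct <- cmp
    summary$comparison <- list(gs_diff = cmp$gs_diff, gs_p = cmp$gs_p,
                               omnibus_p = cmp$omnibus_p,
                               edges_sig = sum(cmp$per_edge$p_adj < 0.05))
  } else {
    summary$comparison <- "skipped (n_perm = 0)"
  }

  clpn <- stage("clpn", fit_clpn(matched, folds = config$folds,
                                 seed = child_seed(config$seed, 15),
                                 lambda_rule = config$lambda_rule))
  write.csv(clpn$B_hat, file.path(config$out_dir, "clpn_matrix.csv"))
  pt <- prediction_table(clpn)
  utils::write.table(pt, file.path(config$out_dir, "clpn_predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ei <- clpn_centralities(clpn)
  write.csv(ei, file.path(config$out_dir, "clpn_influence.csv"),
            row.names = FALSE)
  res$clpn <- clpn
  cross <- pt[!pt$autoregressive, , drop = FALSE]
  summary$clpn <- list(
    cross_lags = nrow(cross),
    top_predictions = utils::head(
      cross[order(-abs(cross$weight)), c("from", "to", "weight")], 5),
    influence = ei)

  stage("report", {
    write_json_file(summary, file.path(config$out_dir, "summary.json"))
    write_summary_md(summary, file.path(config$out_dir, "summary.md"))
  })
  res$summary <- summary
  invisible(res)
}

write_summary_md <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# Two-wave network analysis summary")
  w("")
  w("Master seed: ", s$seed)
  w("")
  w("## Sample")
  w("- T1: ", s$qc$t1$n_retained, "/", s$qc$t1$n_input, " records retained")
  w("- T2: ", s$qc$t2$n_retained, "/", s$qc$t2$n_input, " records retained")
  w("- matched across waves: ", s$matched$matched)
  w("")
  w("## Networks")
  w("- T1: ", s$network$t1$edges, " edges (density ",
    round(s$network$t1$density, 3), "), global strength ",
    round(s$network$t1$global_strength, 3))
  w("- T2: ", s$network$t2$edges, " edges (density ",
    round(s$network$t2$density, 3), "), global strength ",
    round(s$network$t2$global_strength, 3))
  w("- strength order (T1): ", paste(s$strength_order$t1, collapse = " > "))
  w("")
  w("## Stability (CS coefficients)")
  w("- T1: ", paste(names(s$cs$t1), unlist(s$cs$t1), sep = "=",
                    collapse = ", "))
  w("- T2: ", paste(names(s$cs$t2), unlist(s$cs$t2), sep = "=",
                    collapse = ", "))
  w("")
  w("## Wave comparison")
  if (is.character(s$comparison)) {
    w("- ", s$comparison)
  } else {
    w("- global strength |diff| = ", round(s$comparison$gs_diff, 3),
      ", p = ", round(s$comparison$gs_p, 4))
    w("- edges with adjusted p < 0.05: ", s$comparison$edges_sig)
  }
  w("")
  w("## Cross-lagged network")
  w("- cross-lagged edges: ", s$clpn$cross_lags)
  for (i in seq_len(nrow(s$clpn$top_predictions))) {
    r <- s$clpn$top_predictions[i, ]
    w("- ", r$from, " -> ", r$to, ": ", round(r$weight, 3))
  }
  invisible(path)
}
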