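# End-to-end orchestration: simulate -> detect interfaces -> network
# statistics -> divergence accounting -> selection -> contact-preservation
# predictions -> summary report. Fully deterministic under the scenario
# seed; optional per-stage TSV/JSON artifacts, each citing the config hash.

# stable hash of a configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-scenario pipeline
#'
#' Generates a cohort of duplicate pairs with planted truth, detects
#' interfaces geometrically, assembles the evidence-filtered interaction
#' network, and computes the headline quantities: planted-interface
#' recovery, per-pair region substitution counts and relative interface
#' rates (with the twofold exclusion filter), SIR per pair, the
#' interaction-loss rate (both the unbiased planted-truth accounting and
#' the observed-network inference), the interface x interaction 2x2 table,
#' interface substitution matrices, per-site selection proportions compared
#' across groups, and the contact-preservation predictor evaluation.
#'
#' @param config a [scenario_config()].
#' @param margin contact margin in Angstroms (default 0.5).
#' @param network_mode `"MC"` or `"all"`.
#' @param alpha selection significance cutoff (default 0.05).
#' @param hub_threshold hub degree cutoff (default 40).
#' @param rate_filter relative-rate exclusion cap (default 2).
#' @param n_selection_pairs pairs carried into the per-site selection stage
#'   (default `min(n_pairs, 60)`; the scan is the most expensive stage).
#' @param output_dir optional directory for per-stage artifacts.
#' @return Object of class `ppidup_run`.
#' @export
run_pipeline <- function(config = scenario_config(), margin = 0.5,
                         network_mode = c("MC", "all"), alpha = 0.05,
                         hub_threshold = 40, rate_filter = 2,
                         n_selection_pairs = NULL, output_dir = NULL) {
  network_mode <- match.arg(network_mode)
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(n_selection_pairs))
    n_selection_pairs <- min(config$n_pairs, 60L)
  hash <- config_hash(config)
  n <- config$n_pairs

  # stage 1: structures, paralogue models, detected interfaces
  pairs <- vector("list", n)
  detected <- vector("list", n)
  recovery <- logical(n)
  cfg_i <- config
  for (i in seq_len(n)) {
    cfg_i$seed <- derive_seed(config$seed, 10000L + i)
    cx <- gen_toy_complex(cfg_i)
    dp <- gen_duplicate_pair(cx, cx$interface, cfg_i, pair_index = i)
    iface <- identify_interface(
      detect_atom_contacts(cx$structure, "A", "B", margin = margin))
    recovery[i] <- identical(iface$residues_a, cx$interface$residues_a) &&
      identical(iface$residues_b, cx$interface$residues_b)
    pairs[[i]] <- dp
    detected[[i]] <- iface
  }

  # stage 2: contact-preservation outcomes per pair (model contacts once)
  outcomes <- vector("list", n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    dp <- pairs[[i]]
    model_iface <- identify_interface(
      detect_atom_contacts(dp$model, "A", "B", margin = margin))
    tr <- dp$truth
    idx <- which(tr$region == "interface" & (tr$substituted | tr$gap))
    outcomes[[i]] <- lapply(idx, function(s) {
      structure(list(chain = "A", residue_index = s, from_type = tr$from[s],
                     to_type = tr$to[s],
                     preserved = !tr$gap[s] &&
                       s %in% model_iface$residues_a,
                     n_contacts = sum(model_iface$contacts$residue_a == s)),
                class = "contact_outcome")
    })
    predicted[i] <- predict_interaction_conservation(outcomes[[i]])
  }

  # stage 3: interaction network; coupling forces agreement between the
  # planted contact truth and interaction status for a random pair subset
  forced <- rep(NA_character_, n)
  if (config$coupling > 0) {
    forced <- with_seed(derive_seed(config$seed, 4L), {
      couple <- stats::runif(n) < config$coupling
      ifelse(couple, predicted, NA_character_)
    })
  }
  sim <- simulate_interaction_loss(config, forced_status = forced)
  net <- build_network(sim$records, mode = network_mode)

  # stage 4: SIR, loss rate, hubs
  sir <- vapply(pairs, function(dp) {
    r <- compute_sir(dp$gene_a, dp$gene_b, net, strict = FALSE)
    if (is.null(r)) NA_real_ else r$sir
  }, numeric(1))
  pair_df <- data.frame(
    pair = vapply(pairs, function(p) sub("a$", "", p$gene_a), character(1)),
    gene_a = vapply(pairs, `[[`, "", "gene_a"),
    gene_b = vapply(pairs, `[[`, "", "gene_b"), sir = sir)
  loss_truth <- estimate_loss_rate_cohort(sim$truth,
                                          d = config$divergence_time,
                                          source = "truth")
  loss_network <- tryCatch(
    estimate_loss_rate_cohort(pair_df, net, d = config$divergence_time,
                              source = "network"),
    error = function(e) NULL)
  hubs <- find_hubs(net, hub_threshold)

  # stage 5: divergence accounting on detected interfaces
  div_rows <- vector("list", n)
  calls <- vector("list", n)
  pair_data <- vector("list", n)
  for (i in seq_len(n)) {
    dp <- pairs[[i]]
    cols <- map_interface_to_alignment(dp$aligned_seq_a, dp$aligned_seq_b,
                                       detected[[i]]$residues_a)
    cnt <- count_substitutions(dp$aligned_seq_a, dp$aligned_seq_b, cols)
    rate <- relative_interface_rate(cnt, cap = rate_filter)
    calls[i] <- list(classify_pair_divergence(
      pair_df$pair[i], dp$aligned_seq_a, dp$aligned_seq_b, cols,
      dp$gene_a, dp$gene_b, net))
    pair_data[[i]] <- list(aligned_a = dp$aligned_seq_a,
                           aligned_b = dp$aligned_seq_b,
                           columns = cols, call = calls[[i]])
    div_rows[[i]] <- data.frame(
      pair = pair_df$pair[i],
      interface_sites = cnt$n_sites[cnt$region == "interface"],
      interface_subs = cnt$n_subs[cnt$region == "interface"],
      interface_gaps = cnt$n_gaps[cnt$region == "interface"],
      noninterface_sites = cnt$n_sites[cnt$region == "non_interface"],
      noninterface_subs = cnt$n_subs[cnt$region == "non_interface"],
      noninterface_gaps = cnt$n_gaps[cnt$region == "non_interface"],
      ratio = rate$ratio, excluded = rate$excluded,
      interface_status = if (is.null(calls[[i]])) NA_character_
      else calls[[i]]$interface_status,
      interaction_status = if (is.null(calls[[i]])) NA_character_
      else calls[[i]]$interaction_status,
      stringsAsFactors = FALSE)
  }
  divergence <- do.call(rbind, div_rows)
  table1 <- divergence_table(calls)
  sub_matrix <- build_substitution_matrix(pair_data)
  kept <- divergence[!divergence$excluded & is.finite(divergence$ratio), ]
  median_rel_rate <- if (nrow(kept)) stats::median(kept$ratio) else NA_real_
  corr <- tryCatch(
    correlate_divergence_with_sir(kept$ratio,
                                  pair_df$sir[match(kept$pair,
                                                    pair_df$pair)]),
    error = function(e) NULL)

  # stage 6: per-site selection on a pair subset; interface sites evolve as
  # the constrained class, non-interface as the neutral class
  sel_pairs <- seq_len(min(n_selection_pairs, n))
  sel_props <- vector("list", length(sel_pairs))
  cfg_s <- config
  for (j in seq_along(sel_pairs)) {
    i <- sel_pairs[j]
    n_int <- length(pairs[[i]]$interface_sites)
    cfg_s$seed <- derive_seed(config$seed, 20000L + i)
    cfg_s$site_classes <- data.frame(
      label = c("interface", "non_interface"),
      omega = c(config$site_classes$omega[1],
                config$site_classes$omega[nrow(config$site_classes)]),
      n_sites = c(n_int, config$chain_length - n_int))
    sim_aln <- gen_codon_alignment(cfg_s)
    scan <- site_selection_scan(sim_aln$tree, sim_aln$alignment,
                                alpha = alpha)
    props <- region_selection_proportions(scan$class,
                                          sim_aln$site_truth$label)
    props$pair <- pair_df$pair[i]
    props$interaction_status <- if (is.null(calls[[i]])) NA_character_
    else calls[[i]]$interaction_status
    sel_props[[j]] <- props
  }
  selection <- do.call(rbind, sel_props)
  selection_tests <- NULL
  if (!is.null(selection) && nrow(selection)) {
    groups <- split(selection$prop_negative,
                    paste(selection$region, selection$interaction_status,
                          sep = "."))
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2)
      selection_tests <- compare_selection_groups(groups)
  } else {
    selection <- data.frame()
  }

  # stage 7: predictor evaluation against observed interaction status
  observed <- vapply(calls, function(cl)
    if (is.null(cl)) NA_character_ else cl$interaction_status, character(1))
  ok <- !is.na(observed)
  evaluation <- evaluate_predictions(predicted[ok], observed[ok])

  run <- structure(list(
    config = config, config_hash = hash,
    margin = margin, network_mode = network_mode, alpha = alpha,
    rate_filter = rate_filter,
    interface_recovery = mean(recovery),
    pairs = pair_df,
    network = net, hubs = hubs,
    loss_truth = loss_truth, loss_network = loss_network,
    divergence = divergence, table1 = table1,
    median_relative_rate = median_rel_rate,
    sir_correlation = corr,
    substitution_matrix = sub_matrix,
    selection = selection, selection_tests = selection_tests,
    predicted = predicted, observed = observed,
    evaluation = evaluation),
    class = "ppidup_run")

  if (!is.null(output_dir)) write_run_artifacts(run, output_dir)
  run
}

#' Write per-stage artifacts of a pipeline run
#'
#' @param run a `ppidup_run`.
#' @param output_dir directory (created if needed); every file cites the
#'   config hash.
#' @export
write_run_artifacts <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  h <- run$config_hash
  p <- function(f) file.path(output_dir, f)
  cfg <- unclass(run$config)
  jsonlite::write_json(c(cfg, list(config_hash = h)), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_hashed(run$network$edges, p("network_edges.tsv"), h)
  write_tsv_hashed(run$pairs, p("sir.tsv"), h)
  write_tsv_hashed(run$divergence, p("divergence.tsv"), h)
  write_tsv_hashed(run$selection, p("selection.tsv"), h)
  write_tsv_hashed(data.frame(pair = run$pairs$pair,
                              predicted = run$predicted,
                              observed = run$observed),
                   p("predictions.tsv"), h)
  jsonlite::write_json(
    list(config_hash = h,
         interface_recovery = run$interface_recovery,
         loss_rate_truth = run$loss_truth$rate,
         loss_rate_network = if (is.null(run$loss_network)) NULL
         else run$loss_network$rate,
         median_relative_rate = run$median_relative_rate,
         table1 = as.data.frame(as.table(run$table1)),
         sir_correlation = run$sir_correlation,
         hubs = run$hubs,
         evaluation = unclass(run$evaluation)),
    p("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.ppidup_run <- function(x, ...) {
  cat("ppidup pipeline run (config ", substr(x$config_hash, 1, 8), ", ",
      x$config$n_pairs, " pairs, ", x$network_mode, " network)\n", sep = "")
  cat(sprintf("  planted-interface recovery: %.3f\n", x$interface_recovery))
  cat(sprintf("  loss rate (planted-truth):  %.2e /PPI/Myr\n",
              x$loss_truth$rate))
  if (!is.null(x$loss_network))
    cat(sprintf("  loss rate (network route):  %.2e /PPI/Myr\n",
                x$loss_network$rate))
  cat(sprintf("  median relative interface rate: %.3f\n",
              x$median_relative_rate))
  cat("  interface x interaction table:\n")
  print(x$table1)
  cat(sprintf("  predictor: precision=%.3f recall=%.3f F=%.3f\n",
              x$evaluation$precision, x$evaluation$recall,
              x$evaluation$f_score))
  invisible(x)
}

#' @export
#' @method summary ppidup_run
summary.ppidup_run <- function(object, ...) {
  x <- object
  out <- list(config_hash = x$config_hash,
              n_pairs = x$config$n_pairs,
              interface_recovery = x$interface_recovery,
              loss_rate_truth = x$loss_truth$rate,
              loss_rate_network = if (is.null(x$loss_network)) NA_real_
              else x$loss_network$rate,
              median_relative_rate = x$median_relative_rate,
              table1 = x$table1,
              sir_correlation = x$sir_correlation,
              f_score = x$evaluation$f_score)
  class(out) <- "summary.ppidup_run"
  out
}

#' @export
print.summary.ppidup_run <- function(x, ...) {
  utils::str(x, give.attr = FALSE)
  invisible(x)
}
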