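# End-to-end design pipeline: pocket -> backbones -> clusters -> extensions
# -> graft -> clash screen -> sequence design -> metrics -> funnel.

#' Pipeline configuration
#'
#' All stage parameters in one declarative object. The criterion constants
#' default to the study conditions: 4.5 Angstrom ligand contacts, 3.5
#' Angstrom / 135 degree hydrogen bonds, 1.4 Angstrom solvent probe, 90th
#' percentile metric cut.
#'
#' @param ring_size macrocycle ring size (default 6).
#' @param n_samples backbones to sample (default 200).
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param keep_extensions extension candidates kept after ranking (default 4).
#' @param torsion_samples_per_identity extension grid samples per identity.
#' @param max_designs cap on models carried into sequence design (desk-scale
#'   budget; lowest-clash models are kept).
#' @param design_rounds annealing outer rounds per design.
#' @param q percentile-filter quantile.
#' @param target_count minimum percentile-filter survivors.
#' @param k final diversity-selection size.
#' @param contact_cutoff loop/ligand contact cutoff, Angstrom.
#' @param hbond an [hbond_criterion()].
#' @param probe solvent probe radius, Angstrom.
#' @param weights an [energy_weights()].
#' @param pocket a [toy_pocket_spec()] (the fixture receptor; supply
#'   `receptor`/`anchor` to [run_pipeline()] to use real structures).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ring_size = 6L, n_samples = 200L, seed = 1L,
                            keep_extensions = 4L,
                            torsion_samples_per_identity = 10L,
                            max_designs = 36L, design_rounds = 1L,
                            q = 0.90, target_count = 20L, k = 6L,
                            contact_cutoff = 4.5,
                            hbond = hbond_criterion(3.5, 135),
                            probe = 1.4,
                            weights = energy_weights(),
                            pocket = toy_pocket_spec()) {
  structure(list(ring_size = ring_size, n_samples = n_samples, seed = seed,
                 keep_extensions = keep_extensions,
                 torsion_samples_per_identity = torsion_samples_per_identity,
                 max_designs = max_designs, design_rounds = design_rounds,
                 q = q, target_count = target_count, k = k,
                 contact_cutoff = contact_cutoff, hbond = hbond,
                 probe = probe, weights = weights, pocket = pocket),
            class = "pipeline_config")
}

.stage_log <- function(report, stage, n_in, n_out, note = "") {
  line <- sprintf("%-12s in=%-5d out=%-5d %s", stage, n_in, n_out, note)
  report$log <- c(report$log, line)
  report$counts[[stage]] <- n_out
  report
}

#' Run the design pipeline end to end
#'
#' Executes the full funnel and returns a `filter_report` whose survivor sets
#' are nested across stages. Fully reproducible from the configuration alone.
#'
#' @param config a [pipeline_config()].
#' @param receptor optional [structure3d()] with ECL2/ECL3 annotations
#'   (default: the toy pocket from `config$pocket`).
#' @param anchor optional [anchor_stub()] posed in the receptor frame
#'   (default: the toy anchor).
#' @param verbose print stage log lines as they happen.
#' @return object of class `filter_report`: `counts` (per stage), `log`,
#'   `table` (the design metric table), `percentile` (a `filter_result`),
#'   `loop_survivors`, `final` (selected design ids), `models` (the designed
#'   conjugate models, by id), `pocket` (the pocket measurement).
#' @export
run_pipeline <- function(config = pipeline_config(), receptor = NULL,
                         anchor = NULL, verbose = FALSE) {
  report <- list(counts = list(), log = character())
  say <- function(...) if (verbose) cat(sprintf(...), "\n")

  # stage 1: pocket
  if (is.null(receptor)) receptor <- make_toy_pocket(config$pocket, config$probe)
  if (is.null(anchor))
    anchor <- make_toy_anchor(amine_pos = c(0, 0, config$pocket$anchor_z))
  pocket <- pocket_volume(receptor, seed_point = c(0, 0, 0),
                          grid = 0.5, probe = config$probe)
  report <- .stage_log(report, "pocket", 1L, 1L,
                       sprintf("volume=%.0f A^3", pocket$volume))
  say("pocket volume %.0f A^3", pocket$volume)

  # stage 2: extensions off the anchor amine
  cands <- enumerate_extensions(anchor, receptor,
                                config$torsion_samples_per_identity,
                                seed = config$seed + 1L,
                                weights = config$weights)
  kept <- rank_extensions(cands, config$keep_extensions)
  report <- .stage_log(report, "extend", length(cands), length(kept),
                       paste(vapply(kept, function(c) c$label, ""),
                             collapse = " "))
  say("extensions kept: %s", paste(vapply(kept, function(c) c$label, ""),
                                   collapse = ", "))

  # stage 3: backbone library + clustering
  lib <- sample_backbones(config$ring_size, config$n_samples,
                          seed = config$seed + 2L)
  report <- .stage_log(report, "sample", config$n_samples, length(lib))
  clusters <- cluster_backbones(lib, config$hbond)
  reps <- vapply(clusters, function(cl) cl$representative, 0L)
  report <- .stage_log(report, "cluster", length(lib), length(clusters))
  say("%d backbones in %d clusters", length(lib), length(clusters))

  # stage 4: graft cluster representatives onto each kept extension
  models <- list(); meta <- list()
  g_attempt <- 0L
  for (ei in seq_along(kept)) {
    ext <- kept[[ei]]
    for (ri in reps) {
      g_attempt <- g_attempt + 1L
      bb <- lib[[ri]]
      chir_n <- bb$residues$chirality[bb$ring_size]
      frame <- extension_graft_frame(ext, chirality = chir_n,
                                     phi2 = if (chir_n == "D") 120 else -120,
                                     psi_g = 140)
      gb <- graft(bb, frame)
      if (inherits(gb, "graft_failure")) next
      m <- conjugate_model(receptor, anchor, ext, gb)
      models[[length(models) + 1]] <- m
      meta[[length(meta) + 1]] <- list(ext = ext$label, backbone = ri)
    }
  }
  report <- .stage_log(report, "graft", g_attempt, length(models))
  say("%d/%d grafts accepted", length(models), g_attempt)

  # stage 5: clash screen (+ desk-scale cap into design)
  clash <- lapply(models, clash_screen)
  pass <- vapply(clash, function(c) c$pass, TRUE)
  counts <- vapply(clash, function(c) c$count, 0L)
  keep_idx <- which(pass)
  report <- .stage_log(report, "clash", length(models), length(keep_idx))
  if (length(keep_idx) > config$max_designs)
    keep_idx <- keep_idx[order(counts[keep_idx])][seq_len(config$max_designs)]
  models <- models[keep_idx]; meta <- meta[keep_idx]
  report <- .stage_log(report, "design_cap", length(pass), length(models))
  say("%d models into design", length(models))

  # stage 6: sequence design + metrics
  rows <- list(); designed <- list()
  for (i in seq_along(models)) {
    dr <- design_sequence(models[[i]], weights = config$weights,
                          n_outer_rounds = config$design_rounds,
                          seed = config$seed + 100L + i)
    dm <- dr$model
    met <- interface_metrics(dm, config$weights)
    sq <- dr$sequence
    seq_str <- paste(ifelse(sq$chirality == "D",
                            tolower(substr(sq$identity, 1, 1)),
                            substr(sq$identity, 1, 1)), collapse = "")
    ctc <- loop_contacts(dm, cutoff = config$contact_cutoff)
    rows[[i]] <- cbind(data.frame(id = i, extension = meta[[i]]$ext,
                                  backbone = meta[[i]]$backbone,
                                  sequence = seq_str,
                                  bins = dm$peptide_bins,
                                  contacts = paste(ctc, collapse = ";"),
                                  stringsAsFactors = FALSE),
                       met)
    designed[[i]] <- dm
  }
  tab <- do.call(rbind, rows)
  report <- .stage_log(report, "metrics", length(models),
                       if (is.null(tab)) 0L else nrow(tab))
  if (is.null(tab) || !nrow(tab)) stop("pipeline produced no scored designs")

  # stage 7: the funnel
  pf <- percentile_filter(tab, metric_spec(), q = config$q,
                          target_count = min(config$target_count, nrow(tab)))
  report <- .stage_log(report, "percentile", nrow(tab), length(pf$ids),
                       sprintf("q=%.3f", pf$q))
  sub <- tab[tab$id %in% pf$ids, , drop = FALSE]
  lc <- loop_contact_filter(designed[sub$id], cutoff = config$contact_cutoff)
  sub2 <- sub[lc, , drop = FALSE]
  report <- .stage_log(report, "loops", nrow(sub), nrow(sub2))
  if (!nrow(sub2)) {
    final <- integer()
  } else {
    final <- diversity_select(sub2, k = config$k)
  }
  report <- .stage_log(report, "select", nrow(sub2), length(final))
  say("final selection: %s", paste(final, collapse = ", "))

  structure(list(counts = report$counts, log = report$log, table = tab,
                 percentile = pf, loop_survivors = sub2$id, final = final,
                 models = designed, pocket = pocket, config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write the design metric table as tab-separated text
#'
#' Stable column order: id, total_score, ddg, sc, interface_area, cms,
#' buried_unsats, then bookkeeping columns.
#'
#' @param report a `filter_report` (or its `table`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(report, path) {
  tab <- if (inherits(report, "filter_report")) report$table else report
  lead <- c("id", "total_score", "ddg", "sc", "interface_area", "cms",
            "buried_unsats")
  tab <- tab[, c(lead, setdiff(names(tab), lead)), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
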