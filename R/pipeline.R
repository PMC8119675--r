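#' Z-score matrix of a recovery time course
#'
#' Converts each time point's raw track to RPKM and z-scales it over
#' autosomal bins, returning a bins x time matrix (columns named by hour, in
#' chromosome order).
#'
#' @param tracks Named list (hour -> raw `BinnedTrack`) as produced by
#'   [simulate_recovery()] or built from real data.
#' @return Numeric matrix, one row per autosomal bin.
#' @export
recovery_z_matrix <- function(tracks) {
  cols <- lapply(tracks, function(tr) {
    z <- zscale_track(rpkm_track(tr))
    unlist(z$values, use.names = FALSE)
  })
  z <- do.call(cbind, cols)
  colnames(z) <- names(tracks)
  z
}

#' Write a full synthetic dataset to disk
#'
#' Emits the standard interchange files for one simulated experiment:
#' per-condition ChIP count bedGraphs, per-chromosome COO contact matrices,
#' gene annotation BED6, DE table TSV, and a ground-truth JSON (planted
#' domains, labels, gene classes).
#'
#' @param truth A `sim_truth` after [simulate_genes()].
#' @param out_dir Output directory (created).
#' @param conditions Conditions to emit.
#' @return Invisibly, a named list of written paths.
#' @export
simulate_dataset <- function(truth, out_dir,
                             conditions = rownames(truth$config$retention)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cond in conditions) {
    tr <- simulate_chip(truth, cond, mark = "me2")
    p <- file.path(out_dir, sprintf("chip_me2_%s.bedgraph", cond))
    write_track(tr, p); paths[[paste0("me2_", cond)]] <- p
    tr3 <- simulate_chip(truth, cond, mark = "me3")
    p3 <- file.path(out_dir, sprintf("chip_me3_%s.bedgraph", cond))
    write_track(tr3, p3); paths[[paste0("me3_", cond)]] <- p3
    for (chrom in truth$genome$chroms) {
      m <- simulate_contacts(truth, cond, chrom)
      pc <- file.path(out_dir, sprintf("contacts_%s_%s.coo", cond, chrom))
      write_contact_matrix(m, pc)
      paths[[paste0("hic_", cond, "_", chrom)]] <- pc
    }
  }
  g <- truth$genes
  gb <- file.path(out_dir, "genes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom,
                     as.integer(ifelse(g$strand == "-", g$tss - 1999,
                                       g$tss)),
                     as.integer(ifelse(g$strand == "-", g$tss + 1,
                                       g$tss + 2000)),
                     g$gene_id, g$strand), gb)
  paths$genes <- gb
  de <- file.path(out_dir, "de_table.tsv")
  write_tsv(truth$de_table[c("gene_id", "contrast", "log2fc", "de_flag")],
            de)
  paths$de_table <- de
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(
      seed = truth$config$seed,
      chrom_lengths = as.list(truth$genome$lengths),
      domains = truth$domains, satellite = truth$satellite,
      labels = truth$labels, gene_classes = truth$genes$class),
      gt, auto_unbox = TRUE, digits = NA)
    paths$ground_truth <- gt
  }
  invisible(paths)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' End-to-end composition of every stage on files written by
#' [simulate_dataset()]: domain calling per condition (normalize, cap, HMM
#' with pooled parameters, connect), differential domain loss of the
#' inhibitor-resistant domains in the inhibitor-treated knockout,
#' compartment scoring per condition (balance, O/E, PC1 oriented by planted
#' A labels), the 100-kb join of methylation change with compartment change,
#' gene selection, and the upregulated-gene compartment shift.  All outputs
#' plus a resolved-config snapshot and run log land in `out_dir`.
#'
#' @param config A [sim_config()]; its seed fixes every stream.
#' @param out_dir Output directory.
#' @param baseline,treated Conditions joined in the integration stage.
#' @param diff_ref,diff_target Conditions for differential domain loss
#'   (reference domains are called in `diff_ref`).
#' @return A list of stage results (`domain_calls`, `lost`, `scores`,
#'   `join`, `summaries`, `gene_selection`, `shift`, `paths`).
#' @export
run_pipeline <- function(config, out_dir, baseline = "WT",
                         treated = "UNC", diff_ref = "UNC",
                         diff_target = "UNC_KO") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE)
  cat(sprintf("domainscape run, seed %d, %s\n", config$seed,
              format(Sys.time())), file = log)
  truth <- simulate_genome(config)
  truth <- simulate_genes(truth)
  conds <- unique(c(baseline, treated, diff_ref, diff_target))
  input_dir <- file.path(out_dir, "inputs")
  simulate_dataset(truth, input_dir, conditions = conds)
  genome <- truth$genome
  stage <- function(name, expr) {
    logf("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  # --- domains ---------------------------------------------------------
  tracks <- list(); calls <- list()
  stage("domains", {
    for (cond in conds) {
      tracks[[cond]] <- read_track(
        file.path(input_dir, sprintf("chip_me2_%s.bedgraph", cond)),
        genome, config$chip_bin, units = "raw",
        total_reads = config$library_size)
      calls[[cond]] <- call_domains(tracks[[cond]])
      write_domains(calls[[cond]]$domains,
                    file.path(out_dir, sprintf("domains_%s.bed", cond)))
      logf("  %s: %d domains", cond, nrow(calls[[cond]]$domains))
    }
  })
  # --- differential loss ----------------------------------------------
  lost <- stage("diffdomains", {
    d <- call_lost_domains(calls[[diff_ref]]$domains, tracks[[diff_ref]],
                           tracks[[diff_target]])
    d <- conserved_domains(d, calls[[diff_target]]$domains)
    write_domains(d, file.path(out_dir, "domains_diff.bed"))
    logf("  lost %d / conserved %d of %d", sum(d$status == "lost"),
         sum(d$status == "conserved"), nrow(d))
    d
  })
  # --- compartments ----------------------------------------------------
  orient <- lapply(genome$chroms, function(ch)
    as.numeric(truth$labels[[ch]] == "A"))
  names(orient) <- genome$chroms
  scores <- list()
  stage("compartments", {
    for (cond in c(baseline, treated)) {
      mats <- lapply(genome$chroms, function(ch)
        read_contact_matrix(
          file.path(input_dir, sprintf("contacts_%s_%s.coo", cond, ch)),
          config$hic_bin, ch, genome))
      names(mats) <- genome$chroms
      scores[[cond]] <- compartment_scores_genome(mats, orient, genome)
    }
  })
  # --- integration -----------------------------------------------------
  res <- stage("integration", {
    rp <- lapply(c(baseline, treated), function(cond)
      rpkm_track(rebin_track(tracks[[cond]], config$hic_bin)))
    names(rp) <- c(baseline, treated)
    fr <- lapply(c(baseline, treated), function(cond)
      domain_fraction_per_bin(calls[[cond]]$domains, genome,
                              config$hic_bin))
    names(fr) <- c(baseline, treated)
    join <- build_join_table(scores[[baseline]], scores[[treated]],
                             rp[[baseline]], rp[[treated]],
                             fr[[baseline]], fr[[treated]])
    write_tsv(join, file.path(out_dir, "join_table.tsv"))
    list(join = join,
         by_dscore = delta_group_summary(join, "dscore", "drpkm"),
         by_dfrac = delta_group_summary(join, "dfrac", "dscore",
                                        edges = c(-0.5, -0.25, 0)),
         b_to_a = b_to_a_enrichment(join))
  })
  # --- genes -----------------------------------------------------------
  genes <- read_genes_bed(file.path(input_dir, "genes.bed"), genome)
  de <- read_de_table(file.path(input_dir, "de_table.tsv"))
  sel <- stage("genes", {
    me3_tracks <- lapply(conds, function(cond) read_track(
      file.path(input_dir, sprintf("chip_me3_%s.bedgraph", cond)),
      genome, config$chip_bin, units = "raw",
      total_reads = config$library_size))
    names(me3_tracks) <- conds
    me3_calls <- lapply(me3_tracks, function(tr) call_domains(tr)$domains)
    s <- select_setdb1_dependent_genes(
      genes, calls[[diff_ref]]$domains, calls[[diff_target]]$domains,
      me3_calls, tracks[[diff_ref]], tracks[[diff_target]], me3_tracks)
    write_tsv(s, file.path(out_dir, "selected_genes.tsv"))
    logf("  %d genes selected", sum(s$selected))
    s
  })
  up <- de$gene_id[de$contrast == treated & de$de_flag == "upregulated"]
  shift <- stage("gene_shift", {
    gene_compartment_shift(genes, up, scores[[baseline]],
                           scores[[treated]], seed = config$seed)
  })
  snapshot <- file.path(out_dir, "resolved_config.json")
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(
      c(config[!vapply(config, is.matrix, TRUE)],
        list(retention = as.data.frame(config$retention),
             baseline = baseline, treated = treated)),
      snapshot, auto_unbox = TRUE, digits = NA)
  logf("done")
  list(truth = truth, domain_calls = calls, lost = lost, scores = scores,
       join = res$join, summaries = res[c("by_dscore", "by_dfrac",
                                          "b_to_a")],
       gene_selection = sel, shift = shift, out_dir = out_dir)
}
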