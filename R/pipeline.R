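# End-to-end orchestration: simulate (or load) inputs, run the rhythm,
# variability, coupling, stratification and phase-enrichment stages in
# dependency order, and write every artifact plus a machine-readable JSON
# manifest (paths, parameters, seed, md5 checksums) and a human-readable
# log. Identical configuration and seed give checksum-identical output.

#' Build a pipeline configuration
#'
#' A flat list of stage toggles, thresholds and either input paths or
#' simulation configurations. Validation happens up front in
#' [run_pipeline()], before any stage runs.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed governing every stochastic stage.
#' @param stages Named logical vector toggling `simulate`, `rhythms`,
#'   `divvar`, `windows`, `couple`, `stratify`, `psea`, `psea_compare`.
#' @param bulk_sim A [bulk_sim_config()] (used when `simulate` is on).
#' @param cell_sim A [cell_sim_config()].
#' @param psea_sim List of arguments for [simulate_phase_table()]
#'   (`n_sets`, `genes_per_set`, `clustered_sd`, `old_shift` hours applied
#'   to the old group's clustered centers).
#' @param inputs Named list of paths (`expr`, `meta`, `cells`, `gmt`,
#'   `phases_young`, `phases_old`) used for stages whose inputs are not
#'   simulated.
#' @param alpha,resid_threshold Cosinor classification thresholds.
#' @param epsilon Stratification band half-width (log units).
#' @param min_overlap,fdr Phase-set enrichment thresholds.
#' @param pair Length-2 character vector: clock gene (x), senescence gene
#'   (y) for coupling and stratification.
#' @param group_by Metadata columns defining cosinor/coupling groups.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            stages = c(simulate = TRUE, rhythms = TRUE,
                                       divvar = TRUE, windows = TRUE,
                                       couple = TRUE, stratify = TRUE,
                                       psea = TRUE, psea_compare = TRUE),
                            bulk_sim = bulk_sim_config(seed = seed),
                            cell_sim = cell_sim_config(seed = seed + 1),
                            psea_sim = list(n_sets = 60, genes_per_set = 30,
                                            clustered_sd = 1,
                                            old_shift = 4),
                            inputs = list(),
                            alpha = 0.05, resid_threshold = 0.05,
                            epsilon = 0.5, min_overlap = 10, fdr = 0.05,
                            pair = c("Bmal1", "Cdkn1a"),
                            group_by = "age_group") {
  if (missing(outdir)) stop("outdir is required")
  defaults <- c(simulate = TRUE, rhythms = TRUE, divvar = TRUE,
                windows = TRUE, couple = TRUE, stratify = TRUE,
                psea = TRUE, psea_compare = TRUE)
  defaults[names(stages)] <- stages
  list(outdir = outdir, seed = seed, stages = defaults,
       bulk_sim = bulk_sim, cell_sim = cell_sim, psea_sim = psea_sim,
       inputs = inputs, alpha = alpha, resid_threshold = resid_threshold,
       epsilon = epsilon, min_overlap = min_overlap, fdr = fdr,
       pair = pair, group_by = group_by)
}

validate_pipeline_config <- function(cf) {
  st <- cf$stages
  if (is.null(cf$seed) && isTRUE(st[["simulate"]]))
    stop("a seed is mandatory when simulation is enabled")
  needs_bulk <- any(st[c("rhythms", "divvar", "windows", "couple")])
  if (needs_bulk && !st[["simulate"]] &&
      (is.null(cf$inputs$expr) || is.null(cf$inputs$meta)))
    stop("bulk stages enabled but no expression/metadata input and ",
         "simulation is off")
  if (st[["stratify"]] && !st[["simulate"]] && is.null(cf$inputs$cells))
    stop("stratify enabled but no cells input and simulation is off")
  if (st[["psea"]] && !st[["simulate"]] &&
      (is.null(cf$inputs$gmt) || is.null(cf$inputs$phases_young)))
    stop("psea enabled but no gmt/phase-table input and simulation is off")
  if (st[["psea_compare"]] && !st[["psea"]])
    stop("psea_compare requires the psea stage")
  invisible(cf)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate, rhythms,
#' divvar, windows, couple, stratify, psea, psea-compare), writes one TSV
#' per result plus `manifest.json` (file list with md5 checksums, stage
#' parameters, seed) and `pipeline.log`. A stage failure aborts with the
#' failing stage named; files already written by the failing stage are
#' renamed with a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list with `artifacts`, `checksums`,
#'   `parameters`, `seed`).
#' @export
run_pipeline <- function(config) {
  cf <- validate_pipeline_config(config)
  dir.create(cf$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cf$outdir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
  }
  artifacts <- character(0)
  stage_files <- character(0)
  register <- function(path) {
    artifacts <<- c(artifacts, path)
    stage_files <<- c(stage_files, path)
    path
  }
  run_stage <- function(name, fn) {
    stage_files <<- character(0)
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      for (f in stage_files)
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                     conditionMessage(e))), log_path)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage ", name, ": done")
    invisible(ok)
  }
  st <- cf$stages
  out <- function(f) file.path(cf$outdir, f)
  say("pipeline seed: ", cf$seed)
  say("thresholds: alpha=", cf$alpha, " resid_threshold=",
      cf$resid_threshold, " epsilon=", cf$epsilon, " min_overlap=",
      cf$min_overlap, " fdr=", cf$fdr)

  dataset <- NULL; cells <- NULL; phases <- list(); sets <- NULL

  if (st[["simulate"]]) run_stage("simulate", function() {
    bulk <- simulate_bulk_timecourse(cf$bulk_sim)
    dataset <<- bulk$dataset
    write_expression_matrix(dataset, register(out("expr.tsv")))
    write_sample_metadata(dataset$samples, register(out("meta.tsv")))
    utils::write.table(bulk$truth, register(out("truth_genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cp <- simulate_cell_pairs(cf$cell_sim)
    cells <<- cp$cells
    utils::write.table(cp$cells, register(out("cells.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cp$truth, register(out("truth_cells.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ps <- cf$psea_sim
    young <- simulate_phase_table(ps$n_sets, ps$genes_per_set,
                                  ps$clustered_sd, seed = cf$seed + 2)
    old <- simulate_phase_table(ps$n_sets, ps$genes_per_set,
                                ps$clustered_sd, seed = cf$seed + 2,
                                center_shift = ps$old_shift)
    phases <<- list(young = young$phases, old = old$phases)
    sets <<- young$sets
    write_phase_table(young$phases, register(out("phases_young.tsv")))
    write_phase_table(old$phases, register(out("phases_old.tsv")))
    write_gmt(sets, register(out("sets.gmt")))
    say("simulated ", nrow(dataset$matrix), " genes x ",
        ncol(dataset$matrix), " bulk samples; ", nrow(cp$cells),
        " cells; ", length(sets$sets), " gene sets")
  })

  needs_bulk <- any(st[c("rhythms", "divvar", "windows", "couple")])
  if (needs_bulk && is.null(dataset)) {
    m <- read_expression_matrix(cf$inputs$expr)
    dataset <- expression_dataset(m, read_sample_metadata(cf$inputs$meta))
  }
  if (st[["stratify"]] && is.null(cells))
    cells <- utils::read.delim(cf$inputs$cells)
  if (st[["psea"]] && !length(phases)) {
    phases$young <- read_phase_table(cf$inputs$phases_young)
    if (!is.null(cf$inputs$phases_old))
      phases$old <- read_phase_table(cf$inputs$phases_old)
    sets <- read_gmt(cf$inputs$gmt)
  }

  if (st[["rhythms"]]) run_stage("rhythms", function() {
    res <- cosinor_by_gene(dataset, group_by = cf$group_by,
                           alpha = cf$alpha,
                           resid_threshold = cf$resid_threshold,
                           seed = cf$seed + 3)
    utils::write.table(res, register(out("rhythms.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("rhythms: ", sum(res$is_circadian), "/", nrow(res),
        " gene-group fits classified circadian")
  })

  if (st[["divvar"]]) run_stage("divvar", function() {
    res <- dv_by_gene(dataset)
    utils::write.table(res, register(out("divvar.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("divvar: ", sum(res$fdr < cf$fdr), " genes at FDR < ", cf$fdr)
  })

  if (st[["windows"]]) run_stage("windows", function() {
    genes <- intersect(cf$pair, dataset$gene_ids)
    if (!length(genes)) genes <- utils::head(dataset$gene_ids, 4)
    res <- do.call(rbind, lapply(split(seq_len(nrow(dataset$samples)),
                                       dataset$samples$age_group),
                                 function(idx) {
      keep <- seq_len(ncol(dataset$matrix)) %in% idx
      w <- phase_windows(dataset, genes, subset = keep)
      cbind(age_group = dataset$samples$age_group[idx][1], w)
    }))
    utils::write.table(res, register(out("windows.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  if (st[["couple"]]) run_stage("couple", function() {
    res <- couple_genes(dataset, cf$pair[1], cf$pair[2],
                        group_by = cf$group_by)
    utils::write.table(res, register(out("coupling.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fits <- attr(res, "fits")
    grp <- names(fits)
    young <- fits[[grep("young", grp)[1]]]
    old <- fits[[grep("old", grp)[1]]]
    if (!is.null(young) && !is.null(old)) {
      ct <- coupling_contrast(young, old)
      utils::write.table(as.data.frame(unclass(ct)),
                         register(out("coupling_contrast.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("coupling contrast: delta_R=", signif(ct$delta_R, 4),
          " delta_intercept=", signif(ct$delta_intercept, 4))
    }
  })

  if (st[["stratify"]]) run_stage("stratify", function() {
    labels <- stratify_populations(cells$x, cells$y, cf$epsilon)
    labelled <- cbind(cells, population = labels)
    utils::write.table(labelled, register(out("cells_labeled.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("stratify: populations ",
        paste(1:3, tabulate(labels, 3), sep = "=", collapse = ", "))
    m <- rbind(x = cells$x, y = cells$y)
    rownames(m) <- cf$pair
    for (pop in 2:3) {
      if (sum(labels == pop) >= 3 && sum(labels == 1) >= 3) {
        de <- population_de(m, labels, ref_pop = 1, test_pop = pop,
                            alpha = cf$fdr)
        utils::write.table(de, register(out(sprintf("de_pop%d_vs_1.tsv",
                                                    pop))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  })

  psea_res <- list()
  if (st[["psea"]]) run_stage("psea", function() {
    for (grp in names(phases)) {
      rec <- phase_records(phases[[grp]])
      res <- pathway_phase_enrichment(rec, sets,
                                      min_overlap = cf$min_overlap,
                                      fdr_threshold = cf$fdr)
      psea_res[[grp]] <<- res
      utils::write.table(res, register(out(sprintf("psea_%s.tsv", grp))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("psea ", grp, ": ", sum(res$significant), "/", nrow(res),
          " sets significant at FDR < ", cf$fdr)
    }
  })

  if (st[["psea_compare"]]) run_stage("psea_compare", function() {
    if (length(psea_res) < 2) {
      say("psea_compare skipped: fewer than two phase tables")
      return(invisible(NULL))
    }
    res <- compare_age_groups(psea_res$young, psea_res$old,
                              fdr_threshold = cf$fdr)
    utils::write.table(res, register(out("psea_compare.tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("psea_compare: ", nrow(res), " pathways retained; categories: ",
        paste(names(table(res$category)), table(res$category), sep = "=",
              collapse = ", "))
  })

  manifest <- list(
    seed = cf$seed,
    parameters = list(alpha = cf$alpha,
                      resid_threshold = cf$resid_threshold,
                      epsilon = cf$epsilon, min_overlap = cf$min_overlap,
                      fdr = cf$fdr, pair = cf$pair,
                      group_by = cf$group_by,
                      stages = as.list(cf$stages)),
    artifacts = basename(artifacts),
    checksums = as.list(setNames(unname(tools::md5sum(artifacts)),
                                 basename(artifacts))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(manifest)
}

#' Run the packaged demo pipeline
#'
#' All-synthetic end-to-end run at the emulated study scale: 2,000 genes
#' over 4 Zeitgeber timepoints x 8 replicates x 2 age groups (64 bulk
#' samples), 5,000 cells, 60 gene sets. Deterministic given the seed.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @return The pipeline manifest, invisibly.
#' @export
demo_pipeline <- function(outdir, seed = 1) {
  run_pipeline(pipeline_config(outdir = outdir, seed = seed))
}
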