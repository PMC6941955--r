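## End-to-end orchestration: simulate? -> quantify -> correct? -> de ->
## switch, with per-stage logs to stderr, a machine-readable stage summary
## (JSON lines), and provenance-stamped TSV outputs. Reruns of the same
## configuration are bit-identical.

log_stage <- function(con, stage, status, detail = "") {
  message(sprintf("[bsjquant] %s: %s %s", stage, status, detail))
  if (!is.null(con)) {
    writeLines(jsonlite::toJSON(list(stage = stage, status = status,
                                     detail = detail), auto_unbox = TRUE), con)
  }
}

#' Run the full quantification pipeline from a configuration
#'
#' Stages (in order): `simulate` (optional; built-in simulator), `quantify`
#' (per library), `correct` (when the configuration pairs a treated with an
#' untreated library), `de` (replicate-free scores + exact tests, or the
#' TMM/NB-GLM route with replicates), `switch` (LC and CTU events). Each
#' stage writes TSV/YAML artifacts into `out_dir` and a line to
#' `stages.jsonl`; any stage failure stops with the failing stage named.
#'
#' Configuration fields (YAML or list): `seed`; either `simulate:` (n_genes,
#' n_circ, chrom_len, read_length, linear_coverage, error_rate, optional
#' `rnase_r: {linear_survival: ...}`) or `genome_fasta`/`gtf`/`bed` plus
#' `libraries:` (id, fastq1, fastq2, role: treated|untreated, condition:
#' case|control).
#'
#' @param cfg path to a YAML configuration or an equivalent named list.
#' @param out_dir output directory (created if needed); defaults to
#'   `cfg$out_dir`.
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  cfg_hash <- NA_character_
  if (is.character(cfg)) {
    cfg_hash <- unname(tools::md5sum(cfg))
    cfg <- read_run_config(cfg)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "stages.jsonl"), "w")
  on.exit(close(con))
  outputs <- list()
  run_stage <- function(stage, expr) {
    log_stage(con, stage, "start")
    res <- tryCatch(expr, error = function(e) {
      log_stage(con, stage, "failed", conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_stage(con, stage, "done")
    res
  }

  libs <- list()   # library_id -> list(reads, role, condition)

  if (!is.null(cfg$simulate)) {
    sim <- run_stage("simulate", {
      sc <- cfg$simulate
      genome <- simulate_genome(
        n_chrom = sc$n_chrom %||% 1L, chrom_len = sc$chrom_len %||% 1e5,
        n_genes = sc$n_genes %||% 20L,
        exons_per_gene = unlist(sc$exons_per_gene %||% c(3L, 8L)),
        seed = seed)
      circs <- simulate_circrnas(genome, n_circ = sc$n_circ %||% 20L,
                                 seed = sub_seed(seed, 1L))
      scfg <- sim_config(
        read_length = sc$read_length %||% 100L,
        linear_coverage = sc$linear_coverage %||% 10,
        error_rate = sc$error_rate %||% 0,
        seed = sub_seed(seed, 2L))
      reads <- simulate_reads(genome, circs, scfg)
      write_gtf(genome, file.path(out_dir, "simulated.gtf"))
      write_fasta(genome$chroms, file.path(out_dir, "simulated.fa"))
      write_bed(circs, file.path(out_dir, "simulated_circ.bed"))
      write_fastq_pair(reads, file.path(out_dir, "sim_untreated"))
      write_tsv(reads$truth, file.path(out_dir, "sim_truth.tsv"),
                seed = seed, cfg_hash = cfg_hash)
      libs[["untreated"]] <- list(reads = reads, role = "untreated",
                                   condition = "control")
      if (!is.null(sc$rnase_r)) {
        tr <- apply_rnase_r(reads,
                            linear_survival = sc$rnase_r$linear_survival %||% 0.25,
                            seed = sub_seed(seed, 3L))
        write_fastq_pair(tr, file.path(out_dir, "sim_treated"))
        write_tsv(tr$truth, file.path(out_dir, "sim_truth_treated.tsv"),
                  seed = seed, cfg_hash = cfg_hash)
        libs[["treated"]] <- list(reads = tr, role = "treated",
                                   condition = "control")
      }
      list(genome = genome, circs = circs)
    })
    genome <- sim$genome
    cands <- sim$circs
  } else {
    loaded <- run_stage("load", {
      genome <- genome_from_files(cfg$genome_fasta, cfg$gtf)
      cands <- read_bed(cfg$bed)
      for (lib in cfg$libraries) {
        libs[[lib$id]] <- list(
          reads = read_fastq_pair(lib$fastq1, lib$fastq2),
          role = lib$role %||% "untreated",
          condition = lib$condition %||% "control")
      }
      list(genome = genome, cands = cands)
    })
    genome <- loaded$genome
    cands <- loaded$cands
  }

  quants <- run_stage("quantify", {
    out <- list()
    for (id in names(libs)) {
      q <- quantify_library(libs[[id]]$reads, genome, cands, library_id = id)
      p <- file.path(out_dir, sprintf("quant_%s.tsv", id))
      write_quant_tsv(q, p, seed = seed, cfg_hash = cfg_hash)
      outputs[[paste0("quant_", id)]] <- p
      out[[id]] <- q
    }
    out
  })

  roles <- vapply(libs, function(l) l$role, character(1))
  if (any(roles == "treated")) {
    run_stage("correct", {
      if (!any(roles == "untreated")) {
        stop("correct mode requires an untreated (RiboMinus) control library")
      }
      tid <- names(libs)[roles == "treated"][1]
      uid <- names(libs)[roles == "untreated"][1]
      qt <- quants[[tid]]
      qu <- quants[[uid]]
      eff <- enrichment_coefficient(qt$bsj, qt$fsj, qu$bsj, qu$fsj)
      model <- fit_gmm(eff)
      write_enrichment_model(model, file.path(out_dir, "enrichment_model.yaml"))
      usable <- qt$fsj > 0
      corrected <- rep(NA_real_, nrow(qt))
      corrected[usable] <- correct_bsj(qt$bsj[usable], qt$fsj[usable],
                                       qu$fsj[usable], model)$estimate
      tab <- as.data.frame(qt)
      tab$corrected_bsj <- corrected
      tab$corrected_cpm <- compute_cpm(ifelse(is.na(corrected), 0, corrected),
                                       attr(qu, "total_mapped"))
      tab$corrected_cpm[is.na(corrected)] <- NA_real_
      p <- file.path(out_dir, "corrected_quant.tsv")
      write_tsv(tab, p, seed = seed, cfg_hash = cfg_hash)
      outputs[["corrected"]] <- p
      outputs[["model"]] <- file.path(out_dir, "enrichment_model.yaml")
    })
  }

  conds <- vapply(libs, function(l) l$condition, character(1))
  if (length(unique(conds)) == 2) {
    run_stage("de", {
      ctrl_ids <- names(libs)[conds == "control"]
      case_ids <- names(libs)[conds == "case"]
      if (length(ctrl_ids) >= 2 && length(case_ids) >= 2) {
        mat <- vapply(quants[c(ctrl_ids, case_ids)], function(q) q$bsj,
                      integer(nrow(cands)))
        rownames(mat) <- cands$id
        gc_mat <- vapply(quants[c(ctrl_ids, case_ids)],
                         function(q) attr(q, "gene_counts"),
                         numeric(length(attr(quants[[1]], "gene_counts"))))
        de <- replicate_de(mat, rep(c("control", "case"),
                                    c(length(ctrl_ids), length(case_ids))),
                           norm_factors = tmm_factors(gc_mat))
      } else {
        de <- differential_table(quants[[ctrl_ids[1]]], quants[[case_ids[1]]],
                                 seed = sub_seed(seed, 4L))
      }
      p <- file.path(out_dir, "de_results.tsv")
      write_tsv(de, p, seed = seed, cfg_hash = cfg_hash)
      outputs[["de"]] <- p
    })
    run_stage("switch", {
      ctrl_ids <- names(libs)[conds == "control"]
      case_ids <- names(libs)[conds == "case"]
      lc <- detect_lc_switching(quants[[case_ids[1]]], quants[[ctrl_ids[1]]])
      ev <- lc
      if ("gene_id" %in% names(quants[[1]])) {
        ctu <- detect_ctu_switching(quants[case_ids], quants[ctrl_ids])
        ev <- rbind(lc, ctu)
      }
      p <- file.path(out_dir, "switch_events.tsv")
      write_tsv(ev, p, seed = seed, cfg_hash = cfg_hash)
      outputs[["switch"]] <- p
    })
  }
  invisible(outputs)
}
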