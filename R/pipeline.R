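#' Run configuration for the full pipeline
#'
#' Bundles file paths, QC and scan parameters and report options.
#' Can be read from / written to a YAML file so that a run is fully
#' described by one configuration.
#'
#' @param vcf Path to the phased VCF.
#' @param pedigree Path to the pedigree TSV.
#' @param litters Optional path to the litter phenotype TSV; when
#'   absent the association stage is skipped.
#' @param genes Optional path to a gene annotation file.
#' @param genes_dialect `"bed"` or `"gff3"`.
#' @param out Output directory.
#' @param population Population label (prefix of haplotype names).
#' @param qc A [qc_params()] object.
#' @param scan A [scan_params()] object.
#' @param traits Traits to contrast for each selected locus.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, pedigree, litters = NULL, genes = NULL,
                       genes_dialect = "bed", out = "lethalscan_out",
                       population = "POP", qc = qc_params(),
                       scan = scan_params(),
                       traits = c("tnb", "nba", "nsb", "mum")) {
  stopifnot(is.character(vcf), is.character(pedigree))
  structure(list(vcf = vcf, pedigree = pedigree, litters = litters,
                 genes = genes, genes_dialect = genes_dialect, out = out,
                 population = population, qc = qc, scan = scan,
                 traits = match.arg(traits, c("tnb", "nba", "nsb", "mum"),
                                    several.ok = TRUE)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file with keys matching the
#'   [run_config()] arguments (`qc` and `scan` as nested maps).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc <- do.call(qc_params, if (is.null(y$qc)) list() else y$qc)
  sc <- if (is.null(y$scan)) list() else y$scan
  if (!is.null(sc$window_sizes)) sc$window_sizes <- as.numeric(sc$window_sizes)
  scan <- do.call(scan_params, sc)
  args <- y[setdiff(names(y), c("qc", "scan"))]
  do.call(run_config, c(args, list(qc = qc, scan = scan)))
}

write_run_config <- function(config, path) {
  y <- unclass(config)
  y$qc <- unclass(y$qc)
  y$scan <- unclass(y$scan)
  y$qc$autosomes <- as.list(y$qc$autosomes)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Annotate scan records with overlapping genes
#'
#' Lists, per record, the genes whose interval overlaps the record's
#' window under 1-based closed coordinates (window `[start, end)`
#' has closed end `end - 1`); any overlap counts.
#'
#' @param records Scan record or locus data frame (`chrom`, `start`,
#'   `end`).
#' @param intervals Gene intervals from [read_gene_intervals()]
#'   (1-based closed).
#' @return `records` with an added `genes` column (comma-separated
#'   names, empty when none overlap).
#' @export
annotate_genes <- function(records, intervals) {
  records <- as.data.frame(records)
  records$genes <- vapply(seq_len(nrow(records)), function(i) {
    ov <- intervals$chrom == records$chrom[i] &
      intervals$start <= records$end[i] - 1 &
      intervals$end >= records$start[i]
    paste(intervals$name[ov], collapse = ",")
  }, "")
  records
}

#' Join selected loci with their trait effects
#'
#' One row per selected locus and trait, sorted by population, trait,
#' chromosome and window start.
#'
#' @param loci Locus table from [collapse_loci()] (must carry `hap`).
#' @param effects Trait effect table with a `hap` column (and
#'   optionally `population`), e.g. rbind-ed [trait_effect()] rows.
#' @return The joined data frame; loci without effects keep `NA`
#'   effect columns.
#' @export
summary_table <- function(loci, effects = NULL) {
  if (is.null(effects) || nrow(effects) == 0L) {
    out <- loci
    out$trait <- NA_character_
  } else {
    out <- merge(loci, effects, by = "hap", all.x = TRUE,
                 suffixes = c("", ".effect"))
  }
  if (is.null(out$population)) out$population <- sub("[0-9]+$", "", out$hap)
  out <- out[order(out$population, out$trait, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full scan pipeline
#'
#' Executes the stages in order: read inputs, marker QC, animal QC,
#' haplotype scan, locus collapsing, carrier-mating trait contrasts
#' (skipped with a notice when no litter file is configured), gene
#' annotation (when configured) and report writing. Every stage's
#' output, the resolved configuration and a structured run log are
#' written to the output directory; a stage failure aborts with an
#' error naming the stage, retaining partial outputs.
#'
#' @param config A [run_config()] (or path to its YAML form).
#' @return Invisibly, a list with the in-memory stage results
#'   (`panel`, `scan`, `loci`, `effects`, `report`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  t0 <- Sys.time()
  note <- function(stage, ...) {
    msg <- paste(..., collapse = " ")
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, message = msg,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message("[", stage, "] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  write_run_config(config, file.path(config$out, "config.yaml"))

  inp <- stage("read", {
    v <- read_phased_vcf(config$vcf)
    ped <- read_pedigree(config$pedigree)
    lit <- if (!is.null(config$litters)) read_litters(config$litters) else NULL
    list(panel = v$panel, ped = ped, lit = lit)
  })
  note("read", length(inp$panel$ids), "animals,", nrow(inp$panel$map),
       "markers,", nrow(inp$ped), "pedigree rows")

  qc <- stage("qc", {
    fm <- filter_markers(inp$panel, config$qc)
    fa <- filter_animals(fm$panel, config$qc)
    utils::write.table(fm$removed, file.path(config$out, "qc_removed_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fa$removed, file.path(config$out, "qc_removed_animals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fr <- f_coefficient(genotypes(fa$panel))
    utils::write.table(fr, file.path(config$out, "f_coefficient.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(panel = fa$panel, n_markers_removed = nrow(fm$removed),
         n_animals_removed = nrow(fa$removed))
  })
  note("qc", qc$n_markers_removed, "markers and", qc$n_animals_removed,
       "animals removed;", nrow(qc$panel$map), "markers,",
       length(qc$panel$ids), "animals retained")

  fit <- stage("scan", lethal_scan(qc$panel, inp$ped, config$scan,
                                   population = config$population))
  note("scan", fit$n_windows, "windows,", nrow(fit$records),
       "haplotype records,", sum(fit$records$testable), "testable,",
       sum(fit$records$classification %in% c("MH", "DH")), "significant")

  loci <- stage("collapse", collapse_loci(fit))
  note("collapse", nrow(loci), "loci selected")
  if (!is.null(config$genes)) {
    loci <- stage("annotate", {
      gi <- read_gene_intervals(config$genes, config$genes_dialect)
      annotate_genes(loci, gi)
    })
    note("annotate", "gene annotation attached")
  }
  write_scan_table(fit$records, file.path(config$out, "scan_records.tsv"))
  write_scan_table(loci, file.path(config$out, "loci.tsv"))

  effects <- NULL
  if (is.null(inp$lit)) {
    note("assoc", "skipped: no litter file configured")
  } else if (nrow(loci)) {
    effects <- stage("assoc", {
      out <- list()
      for (i in seq_len(nrow(loci))) {
        win <- loci[i, ]
        copies <- diplotype_copies(qc$panel, win, win$allele)
        cls <- classify_matings(inp$lit, copies)
        for (tr in config$traits) {
          eff <- trait_effect(cls, tr)
          eff$hap <- win$hap
          out[[length(out) + 1L]] <- eff
        }
      }
      do.call(rbind, out)
    })
    utils::write.table(effects, file.path(config$out, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("assoc", nrow(effects), "trait contrasts computed")
  }

  report <- stage("report", summary_table(loci, effects))
  utils::write.table(report, file.path(config$out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("report", "written to", config$out)
  logdf <- do.call(rbind, log)
  utils::write.table(logdf, file.path(config$out, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(panel = qc$panel, scan = fit, loci = loci,
                 effects = effects, report = report, log = logdf))
}
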