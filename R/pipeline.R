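#' Read / write pipeline run configuration
#'
#' Flat \code{key = value} text file. Recognized keys: input paths
#' (\code{counts}, \code{samples}, \code{catalog}, \code{annotations} --
#' comma-separated BED paths, \code{alleles}), thresholds
#' (\code{min_dna_count}, \code{min_lib_proportion}, \code{stabilizer},
#' \code{trim_fraction}, \code{ratio_threshold}, \code{min_base_quality},
#' \code{min_af}, \code{maf_threshold}), \code{n_permutations}, \code{seed}
#' and \code{outdir}.
#'
#' @param path Config file path.
#' @param config Named list of settings.
#' @return \code{readRunConfig} returns the config as a named list with
#'   numeric fields coerced; \code{writeRunConfig} invisibly returns
#'   \code{path}.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=(.*)$",
                                    lines))
    bad <- vapply(kv, length, integer(1)) != 3
    if (any(bad))
        stop("cannot parse config line(s): ",
             paste(lines[bad], collapse = "; "))
    cfg <- setNames(lapply(kv, function(x) trimws(x[3])),
                    vapply(kv, `[`, "", 2))
    num <- c("min_dna_count", "min_lib_proportion", "stabilizer",
             "trim_fraction", "ratio_threshold", "min_base_quality",
             "min_af", "maf_threshold", "n_permutations", "seed")
    for (k in intersect(num, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
    cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    flat <- vapply(config, function(v) paste(as.character(v), collapse = ","),
                   "")
    writeLines(paste(names(flat), flat, sep = " = "), path)
    invisible(path)
}

.defaultRunConfig <- function() list(
    min_dna_count = 200, min_lib_proportion = 2^-15, stabilizer = 1000,
    trim_fraction = 0.10, ratio_threshold = 1.5, min_base_quality = 25,
    min_af = 0.01, maf_threshold = 0.1, n_permutations = 20000, seed = 1)

#' Read counts matrix and sample sheet TSVs
#'
#' The counts TSV is a wide matrix with first column \code{amplicon_id} and
#' one column per sample; the sample sheet TSV has columns
#' \code{sample_id}, \code{kind}, \code{replicate} and optionally
#' \code{technical_of}.
#'
#' @param path File path.
#' @return \code{readCountMatrix}: integer matrix; \code{readSampleSheet}:
#'   \code{data.frame}.
#' @export
readCountMatrix <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                      check.names = FALSE)
    if (colnames(tab)[1] != "amplicon_id")
        stop(sprintf("%s: first column must be 'amplicon_id'", path))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$amplicon_id
    if (any(m < 0)) stop(sprintf("%s: negative counts", path))
    m
}

#' @rdname readCountMatrix
#' @export
readSampleSheet <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("sample_id", "kind", "replicate")
    if (!all(need %in% colnames(tab)))
        stop(sprintf("%s: sample sheet needs columns %s", path,
                     paste(need, collapse = ", ")))
    if (!is.null(tab$technical_of))
        tab$technical_of[tab$technical_of == ""] <- NA_character_
    tab
}

.writeTsv <- function(tab, path, header_lines) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header_lines), con)
    write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

.provenance <- function(config, config_path = NULL) {
    md5 <- if (!is.null(config_path)) unname(tools::md5sum(config_path))
           else "none"
    c(sprintf("starrcall %s",
              as.character(utils::packageVersion("starrcall"))),
      sprintf("seed=%d", as.integer(config$seed)),
      sprintf("config_md5=%s", md5))
}

#' Run the full MPRA analysis pipeline
#'
#' Orchestrates catalog loading, QC filtering, activity calling with both
#' models, annotation enrichment (skipped with a logged notice when no
#' annotation sets are configured) and allele summaries, writing a TSV
#' bundle plus a run log and a summary report to \code{outdir}. Outputs
#' carry a provenance header (package version, seed, config hash) and are
#' byte-identical across runs with identical config and seed.
#'
#' @param config Path to a \code{key = value} config file, or a named list
#'   as from [readRunConfig()]. Required keys: \code{counts},
#'   \code{samples}, \code{catalog}, \code{outdir}; optional:
#'   \code{annotations} (comma-separated BED paths), \code{alleles}, and
#'   any threshold overrides.
#' @return Invisibly, a list with elements \code{activity},
#'   \code{enrichment}, \code{alleles}, \code{summary} and \code{outdir}.
#' @export
runPipeline <- function(config) {
    config_path <- NULL
    if (is.character(config) && length(config) == 1) {
        config_path <- config
        config <- readRunConfig(config)
    }
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    for (k in c("counts", "samples", "catalog", "outdir"))
        if (is.null(cfg[[k]]))
            stop("configuration error: missing required key '", k, "'")
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    log_lines <- character()
    note <- function(fmt, ...) {
        log_lines <<- c(log_lines, sprintf(paste0("INFO ", fmt), ...))
    }
    prov <- .provenance(cfg, config_path)

    catalog <- readAmpliconCatalog(cfg$catalog)
    counts <- readCountMatrix(cfg$counts)
    samples <- readSampleSheet(cfg$samples)
    if (!any(samples$kind == "DNA"))
        stop("configuration error: no DNA samples in sample sheet")
    mpra <- MpraExperiment(counts, catalog, samples)
    note("loaded %d amplicons x %d samples", nrow(mpra), ncol(mpra))

    filt <- filterAmplicons(mpra, min_dna_count = cfg$min_dna_count,
                            min_lib_proportion = cfg$min_lib_proportion)
    excl <- metadata(filt)$exclusionLog
    note("filter: removed %d amplicons (%d low_count, %d low_proportion), retained %d",
         nrow(excl), sum(grepl("low_count", excl$rule)),
         sum(grepl("low_proportion", excl$rule)), nrow(filt))
    .writeTsv(as.data.frame(excl), file.path(cfg$outdir, "exclusions.tsv"),
              prov)

    act <- callActivity(filt, stabilizer = cfg$stabilizer,
                        trim_fraction = cfg$trim_fraction,
                        ratio_threshold = cfg$ratio_threshold)
    fit <- metadata(act)$backgroundFit
    note("training set: %d amplicons; model residual sd %.4f",
         length(fit@trainingIds), fit@residualSd)
    .writeTsv(as.data.frame(act), file.path(cfg$outdir, "activity.tsv"),
              prov)
    writeLines(c(paste0("# ", prov),
                 sprintf("intercept = %.10g", fit@coefficients[["intercept"]]),
                 sprintf("slope_dna = %.10g", fit@coefficients[["slope_dna"]]),
                 sprintf("coeff_gc = %.10g", fit@coefficients[["coeff_gc"]]),
                 sprintf("residual_sd = %.10g", fit@residualSd),
                 sprintf("ks_statistic = %.10g", fit@ksStatistic),
                 sprintf("ks_p = %.10g", fit@ksP)),
               file.path(cfg$outdir, "background_model.txt"))

    enr <- NULL
    if (!is.null(cfg$annotations) && nzchar(cfg$annotations)) {
        paths <- strsplit(cfg$annotations, ",")[[1]]
        marks <- lapply(paths, rtracklayer::import)
        names(marks) <- sub("\\.bed$", "", basename(paths))
        enr <- enrichmentAnalysis(act, rowRanges(filt), marks,
                                  n_perm = as.integer(cfg$n_permutations),
                                  seed = as.integer(cfg$seed))
        note("enrichment: %d marks tested with %d permutations",
             nrow(enr), as.integer(cfg$n_permutations))
        .writeTsv(enr, file.path(cfg$outdir, "enrichment.tsv"), prov)
    } else {
        note("enrichment: no annotation sets configured, stage skipped")
    }

    alle <- NULL
    if (!is.null(cfg$alleles) && nzchar(cfg$alleles)) {
        raw <- readAlleleCounts(cfg$alleles)
        filtered <- filterAlleleCounts(raw,
                                       min_base_quality = cfg$min_base_quality,
                                       min_af = cfg$min_af)
        note("alleles: %d observations in, %d biallelic SNPs retained",
             nrow(raw), length(unique(filtered$snp_id)))
        alle <- alleleSummary(filtered, sampleKind(mpra),
                              maf_threshold = cfg$maf_threshold)
        .writeTsv(alle$snps, file.path(cfg$outdir, "alleles.tsv"), prov)
    } else {
        note("alleles: no allele table configured, stage skipped")
    }

    n_p05 <- sum(act$p_model < 0.05)
    n_q01 <- sum(act$q_model < 0.1)
    n_ratio <- sum(act$ratiometric_call)
    conc <- sum(act$p_model < 0.05 & act$ratiometric_call)
    summary_lines <- c(
        paste0("# ", prov),
        sprintf("n_input_amplicons = %d", nrow(mpra)),
        sprintf("n_retained = %d", nrow(filt)),
        sprintf("n_training = %d", length(fit@trainingIds)),
        sprintf("n_significant_p05 = %d", n_p05),
        sprintf("n_significant_q01 = %d", n_q01),
        sprintf("n_ratiometric_active = %d", n_ratio),
        sprintf("n_concordant_models = %d", conc),
        sprintf("min_dna_count = %g", cfg$min_dna_count),
        sprintf("min_lib_proportion = %g", cfg$min_lib_proportion),
        sprintf("stabilizer = %g", cfg$stabilizer),
        sprintf("trim_fraction = %g", cfg$trim_fraction),
        sprintf("ratio_threshold = %g", cfg$ratio_threshold),
        sprintf("n_permutations = %g", cfg$n_permutations),
        sprintf("seed = %d", as.integer(cfg$seed)))
    if (!is.null(enr))
        summary_lines <- c(summary_lines,
                           sprintf("perm_p_%s = %.6g", enr$mark, enr$perm_p))
    writeLines(summary_lines, file.path(cfg$outdir, "summary.txt"))
    writeLines(log_lines, file.path(cfg$outdir, "run.log"))

    invisible(list(activity = act, enrichment = enr, alleles = alle,
                   summary = summary_lines, outdir = cfg$outdir))
}

#' Write simulated inputs as the pipeline's on-disk formats
#'
#' Writes the counts TSV, sample sheet TSV, catalog TSV, truth TSV and
#' (optionally) annotation BED files and an allele TSV for a simulated
#' dataset, so a full pipeline run can be reproduced from plain-text files.
#'
#' @param sim A list with \code{mpra} and \code{truth} as from
#'   [simulateMpra()].
#' @param dir Output directory (created if needed).
#' @param annotations Optional \code{GRangesList} from
#'   [simulateAnnotations()].
#' @param alleles Optional allele table from [simulateAlleles()].
#' @return Named list of written file paths.
#' @export
writeSimulatedInputs <- function(sim, dir, annotations = NULL,
                                 alleles = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    cnt <- data.frame(amplicon_id = rownames(counts(sim$mpra)),
                      counts(sim$mpra), check.names = FALSE)
    paths$counts <- file.path(dir, "counts.tsv")
    write.table(cnt, paths$counts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- colData(sim$mpra)
    ss <- data.frame(sample_id = rownames(cd), kind = cd$kind,
                     replicate = cd$replicate,
                     technical_of = ifelse(is.na(cd$technical_of), "",
                                           cd$technical_of))
    paths$samples <- file.path(dir, "samples.tsv")
    write.table(ss, paths$samples, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$catalog <- file.path(dir, "catalog.tsv")
    writeAmpliconCatalog(rowRanges(sim$mpra), paths$catalog)
    paths$truth <- file.path(dir, "truth.tsv")
    write.table(as.data.frame(sim$truth), paths$truth, sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(annotations)) {
        paths$annotations <- vapply(names(annotations), function(mk) {
            p <- file.path(dir, paste0(mk, ".bed"))
            rtracklayer::export(annotations[[mk]], p, format = "BED")
            p
        }, "")
    }
    if (!is.null(alleles)) {
        paths$alleles <- file.path(dir, "alleles.tsv")
        write.table(alleles, paths$alleles, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    paths
}
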