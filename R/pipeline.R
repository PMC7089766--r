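#' Default pipeline parameters
#'
#' Every tunable used by the analysis stages, with its default: 50 bp
#' coverage bins, >10-fold peak enrichment over control with a 0.1 RPKM
#' control pseudocount, 2 kb spike-in windows, 2.5 kb site flanks, 10-bin
#' resection windows with a >100 bp resected filter, 250 bp summit matching
#' for site overlap, pooled genome-wide species aggregation, unstranded
#' resection.
#'
#' @return Named list of parameter defaults.
#' @export
defaultParameters <- function() {
    list(bin_width = 50L,
         fold_threshold = 10,
         pseudocount_rpkm = 0.1,
         spike_window_bp = 5000L,
         site_flank_bp = 2500L,
         resection_window_bins = 10L,
         resection_min_bp = 100,
         overlap_max_distance = 250L,
         aggregation = "POOLED",
         strand_mode = "unstranded")
}

#' Read a pipeline run configuration
#'
#' @param path Path to a YAML configuration file.
#' @return The configuration as a named list, with defaults filled in for
#'   any parameter not set.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    .fillConfig(cfg)
}

.fillConfig <- function(cfg) {
    par <- defaultParameters()
    for (k in names(cfg$parameters)) par[[k]] <- cfg$parameters[[k]]
    cfg$parameters <- par
    if (is.null(cfg$seed)) cfg$seed <- 1L
    cfg
}

.metaFromRow <- function(row, spikeFraction) {
    sampleMeta(row$sample_id, row$treatment, row$nuclease, row$timepoint,
               spikeInFraction = if (!is.null(row$spike_in_fraction))
                   row$spike_in_fraction else spikeFraction)
}

#' Validate pipeline inputs
#'
#' Checks configuration keys, file existence and parseability, enum values,
#' summit distance to chromosome ends (resection needs 5 kb flanks), and
#' sample pairing: persistence needs a pre-washout ExoVII+ExoT sample per
#' treatment arm, species classification additionally needs 0 hr washout
#' ExoVII+ExoT and ExoT-only samples. Problems are returned as a report,
#' not raised.
#'
#' @param config Configuration list or path to a YAML file.
#' @return data.frame with columns \code{level} (\code{"error"} or
#'   \code{"warning"}) and \code{message}; zero rows when everything checks
#'   out.
#' @export
validateInputs <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- .fillConfig(config)
    rep <- data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE)
    add <- function(level, msg) rbind(rep, data.frame(level = level,
                                                      message = msg,
                                                      stringsAsFactors = FALSE))
    sim <- !is.null(config$simulate)
    if (sim) {
        sc <- config$simulate
        cs <- unlist(sc$chrom_sizes)
        ok <- tryCatch({
            simConfig(chromSizes = cs,
                      nSites = sc$n_sites %||% 200L,
                      nSpikeSites = sc$n_spike_sites %||% 10L,
                      spikeInFraction = sc$spike_in_fraction %||% 0.025,
                      cellsPerSample = sc$cells_per_sample %||% 2000L,
                      backgroundRate = sc$background_rate %||% 0.05,
                      summitJitter = sc$summit_jitter %||% 3L,
                      washoutSurvival = sc$washout_survival %||% 0.5,
                      seed = config$seed)
            TRUE
        }, error = function(e) conditionMessage(e))
        if (!isTRUE(ok)) rep <- add("error", paste("simulate config:", ok))
        samples <- sc$samples
        if (is.null(samples) || length(samples) == 0L)
            rep <- add("error", "simulate config lists no samples")
        sheet <- do.call(rbind, lapply(samples, as.data.frame))
    } else {
        for (key in c("sample_sheet", "sites_bed", "chrom_sizes")) {
            p <- config[[key]]
            if (is.null(p))
                rep <- add("error", paste("missing required config key:", key))
            else if (!file.exists(p))
                rep <- add("error", sprintf("%s file not found: %s", key, p))
        }
        sheet <- NULL
        if (!is.null(config$sample_sheet) && file.exists(config$sample_sheet))
            sheet <- tryCatch(readSampleSheet(config$sample_sheet),
                              error = function(e) {
                                  rep <<- add("error",
                                              paste("sample sheet:",
                                                    conditionMessage(e)))
                                  NULL
                              })
        if (!is.null(sheet)) {
            for (p in sheet$reads_path)
                if (!file.exists(p))
                    rep <- add("error", paste("reads file not found:", p))
        }
        if (!is.null(config$sites_bed) && file.exists(config$sites_bed)) {
            sites <- tryCatch(readSites(config$sites_bed),
                              error = function(e) {
                                  rep <<- add("error", conditionMessage(e))
                                  NULL
                              })
            if (!is.null(sites) && !is.null(config$chrom_sizes) &&
                file.exists(config$chrom_sizes)) {
                cs <- readChromSizes(config$chrom_sizes)
                for (i in seq_along(sites)) {
                    cn <- as.character(seqnames(sites))[i]
                    s0 <- mcols(sites)$summit[i]
                    if (cn %in% names(cs) &&
                        (s0 < 5000 || s0 + 5000 > cs[[cn]]))
                        rep <- add("warning",
                                   sprintf("site %s summit within 5 kb of a chromosome end; resection will skip it",
                                           mcols(sites)$site_id[i]))
                }
            }
        }
    }
    if (!is.null(sheet) && nrow(sheet)) {
        badN <- !sheet$nuclease %in% nucleaseLevels()
        if (any(badN))
            rep <- add("error", sprintf("unknown nuclease '%s' for sample %s",
                                        sheet$nuclease[badN][1L],
                                        sheet$sample_id[badN][1L]))
        badT <- !sheet$timepoint %in% timepointLevels()
        if (any(badT))
            rep <- add("error", sprintf("unknown timepoint '%s' for sample %s",
                                        sheet$timepoint[badT][1L],
                                        sheet$sample_id[badT][1L]))
        if (anyDuplicated(sheet$sample_id))
            rep <- add("error", "duplicate sample_id in sample sheet")
        treated <- !toupper(sheet$treatment) %in% .untreatedLabels
        if (!any(!treated))
            rep <- add("warning",
                       "no untreated control sample: fold-enrichment detection unavailable")
        for (arm in unique(sheet$treatment[treated])) {
            s <- sheet[sheet$treatment == arm, ]
            has <- function(nuc, tp) any(s$nuclease == nuc & s$timepoint == tp)
            if (!has("EXOVII_EXOT", "PRE_WASHOUT"))
                rep <- add("warning", sprintf(
                    "arm %s lacks a PRE_WASHOUT ExoVII+ExoT sample: persistence and species classification unavailable",
                    arm))
            else if (!has("EXOVII_EXOT", "WASHOUT_0H") ||
                     !has("EXOT_ONLY", "WASHOUT_0H"))
                rep <- add("warning", sprintf(
                    "arm %s lacks the 0 hr washout ExoVII+ExoT / ExoT-only pair: species classification unavailable",
                    arm))
        }
    }
    rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## assemble per-sample ReadEndSets either by simulation or from disk
.loadSamples <- function(config, outDir) {
    if (!is.null(config$simulate)) {
        sc <- config$simulate
        cs <- unlist(sc$chrom_sizes)
        simcfg <- simConfig(chromSizes = cs,
                            nSites = sc$n_sites %||% 200L,
                            nSpikeSites = sc$n_spike_sites %||% 10L,
                            spikeInFraction = sc$spike_in_fraction %||% 0.025,
                            cellsPerSample = sc$cells_per_sample %||% 2000L,
                            backgroundRate = sc$background_rate %||% 0.05,
                            summitJitter = sc$summit_jitter %||% 3L,
                            washoutSurvival = sc$washout_survival %||% 0.5,
                            seed = config$seed)
        tr <- sc$truth %||% list()
        gen <- simulateGenome(simcfg,
                              pCleaved = tr$p_cleaved %||% 0.2,
                              fReversible = tr$f_reversible %||% 0.76,
                              fIrreversible = tr$f_irreversible %||% 0.04,
                              fFree = tr$f_free %||% 0.20,
                              resectionMeanBp = tr$resection_mean_bp %||% 500,
                              resectionMaxBp = tr$resection_max_bp %||% 2500)
        sheet <- do.call(rbind, lapply(sc$samples, as.data.frame))
        sheet$spike_in_fraction <- simcfg@spikeInFraction
        metas <- lapply(seq_len(nrow(sheet)), function(i)
            .metaFromRow(sheet[i, ], simcfg@spikeInFraction))
        reads <- lapply(metas, simulateSample, truth = gen$truth,
                        spikeSites = gen$spikeSites, config = simcfg)
        names(reads) <- sheet$sample_id
        paths <- file.path(outDir, paste0(sheet$sample_id, ".bed"))
        for (i in seq_along(reads)) writeBed(reads[[i]], paths[i])
        writeTruth(gen$truth, gen$spikeSites,
                   file.path(outDir, "truth.tsv"))
        sheet$reads_path <- paths
        writeSampleSheet(metas, paths, file.path(outDir, "samples.tsv"))
        flank <- config$parameters$site_flank_bp
        sites <- breakSites(gen$truth$chrom, gen$truth$summit, flank = flank,
                            siteId = gen$truth$site_id, chromSizes = cs)
        writeSites(sites, file.path(outDir, "sites.bed"))
        list(sheet = sheet, reads = reads, sites = sites,
             spikeSites = gen$spikeSites, chromSizes = cs,
             truth = gen$truth)
    } else {
        sheet <- readSampleSheet(config$sample_sheet)
        cs <- readChromSizes(config$chrom_sizes)
        reads <- lapply(seq_len(nrow(sheet)), function(i)
            readEndSet(readBed(sheet$reads_path[i]), chromSizes = cs))
        names(reads) <- sheet$sample_id
        sites <- readSites(config$sites_bed)
        spikeSites <- if (!is.null(config$spike_sites_bed)) {
            sg <- readSites(config$spike_sites_bed)
            data.frame(site_id = mcols(sg)$site_id,
                       chrom = as.character(seqnames(sg)),
                       summit = mcols(sg)$summit, stringsAsFactors = FALSE)
        } else NULL
        list(sheet = sheet, reads = reads, sites = sites,
             spikeSites = spikeSites, chromSizes = cs, truth = NULL)
    }
}

#' Run the full END-seq break-analysis pipeline
#'
#' Orchestrates simulate (optional) -> coverage -> break quantification with
#' spike-in normalization -> persistence -> species classification ->
#' resection, writing tab-separated result tables and a JSON run manifest to
#' the output directory. Deterministic given the configured seed: re-running
#' an unchanged configuration reproduces the output files byte for byte.
#'
#' @param config Configuration list or path to a YAML file (see the package
#'   vignette for the schema; \code{\link{defaultParameters}} lists the
#'   tunables).
#' @param outputDir Overrides \code{config$output_dir}.
#' @return Invisibly, a list with the computed tables: \code{quantified},
#'   \code{persistence}, \code{species}, \code{resection},
#'   \code{stratified}, plus \code{sheet} and (when simulating)
#'   \code{truth}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- .fillConfig(config)
    rep <- validateInputs(config)
    if (any(rep$level == "error"))
        stop("input validation failed:\n  ",
             paste(rep$message[rep$level == "error"], collapse = "\n  "),
             call. = FALSE)
    outDir <- outputDir %||% config$output_dir %||% "."
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    par <- config$parameters

    dat <- .loadSamples(config, outDir)
    sheet <- dat$sheet
    sites <- dat$sites
    if (!is.null(config$blacklist_bed) && file.exists(config$blacklist_bed))
        sites <- subtractBlacklist(sites, readBed(config$blacklist_bed))

    stranded <- identical(par$strand_mode, "stranded")
    tracks <- lapply(dat$reads, coverageFromReads, binWidth = par$bin_width,
                     chromSizes = dat$chromSizes, stranded = stranded)

    spikes <- if (!is.null(dat$spikeSites) && nrow(dat$spikeSites)) {
        lapply(seq_along(tracks), function(i)
            spikeInFactor(tracks[[i]], dat$spikeSites,
                          windowBp = par$spike_window_bp,
                          spikeInFraction = sheet$spike_in_fraction[i] %||% 0.025))
    } else NULL

    treated <- !toupper(sheet$treatment) %in% .untreatedLabels
    controlIdx <- which(!treated)[1]
    control <- if (!is.na(controlIdx)) tracks[[controlIdx]] else NULL

    quantified <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
        q <- quantifyBreaks(tracks[[i]], sites, control = control,
                            spike = if (!is.null(spikes)) spikes[[i]],
                            foldThreshold = par$fold_threshold,
                            pseudocountRpkm = par$pseudocount_rpkm)
        cbind(sample_id = sheet$sample_id[i], q, stringsAsFactors = FALSE)
    }))
    .writeTsv(quantified, file.path(outDir, "quantified.tsv"))

    sigOf <- function(i) {
        q <- quantified[quantified$sample_id == sheet$sample_id[i], ]
        if (!is.null(spikes)) q$cell_percentage else q$rpkm
    }
    findSample <- function(arm, nuc, tp) {
        which(sheet$treatment == arm & sheet$nuclease == nuc &
              sheet$timepoint == tp)[1]
    }

    persistence <- species <- NULL
    arms <- unique(sheet$treatment[treated])
    for (arm in arms) {
        iPre <- findSample(arm, "EXOVII_EXOT", "PRE_WASHOUT")
        if (is.na(iPre)) next
        tpIdx <- c(WASHOUT_0H = findSample(arm, "EXOVII_EXOT", "WASHOUT_0H"),
                   WASHOUT_2H = findSample(arm, "EXOVII_EXOT", "WASHOUT_2H"))
        tpIdx <- tpIdx[!is.na(tpIdx)]
        if (length(tpIdx)) {
            sig <- data.frame(initial = sigOf(iPre))
            for (tp in names(tpIdx)) sig[[tp]] <- sigOf(tpIdx[[tp]])
            rownames(sig) <- mcols(sites)$site_id
            pt <- persistenceTable(sig, initial = "initial")
            pt$records$treatment <- arm
            pt$summary$treatment <- arm
            persistence <- list(
                records = rbind(persistence$records, pt$records),
                summary = rbind(persistence$summary, pt$summary))
        }
        iW0 <- findSample(arm, "EXOVII_EXOT", "WASHOUT_0H")
        iT0 <- findSample(arm, "EXOT_ONLY", "WASHOUT_0H")
        if (!is.na(iW0) && !is.na(iT0)) {
            gw <- classifyGenomewide(sigOf(iPre), sigOf(iW0), sigOf(iT0),
                                     aggregation = par$aggregation)
            species <- rbind(species, data.frame(
                treatment = arm, dsb = dsb(gw),
                reversible = reversibleTop2cc(gw),
                irreversible = irreversibleTop2cc(gw),
                top2cc_total = totalTop2cc(gw), stringsAsFactors = FALSE))
        }
    }
    if (!is.null(persistence)) {
        .writeTsv(persistence$records, file.path(outDir, "persistence.tsv"))
        .writeTsv(persistence$summary,
                  file.path(outDir, "persistence_summary.tsv"))
    }
    if (!is.null(species))
        .writeTsv(species, file.path(outDir, "species.tsv"))

    resection <- NULL
    for (arm in arms) {
        i0 <- findSample(arm, "EXOVII_EXOT", "WASHOUT_0H")
        if (is.na(i0)) next
        rc <- callResection(dat$reads[[i0]], sites,
                            mode = par$strand_mode,
                            minResection = par$resection_min_bp,
                            windowBins = par$resection_window_bins)
        rc$treatment <- arm
        resection <- rbind(resection, rc)
    }
    if (!is.null(resection))
        .writeTsv(resection, file.path(outDir, "resection.tsv"))

    stratified <- NULL
    if (!is.null(resection) && !is.null(persistence)) {
        for (arm in unique(resection$treatment)) {
            pr <- persistence$records[
                persistence$records$treatment == arm &
                persistence$records$timepoint == "WASHOUT_0H", ]
            if (nrow(pr) == 0L) next
            st <- stratifyByResection(resection[resection$treatment == arm, ],
                                      pr)
            st$summary$treatment <- arm
            stratified <- rbind(stratified, st$summary)
        }
        if (!is.null(stratified))
            .writeTsv(stratified, file.path(outDir, "stratified.tsv"))
    }

    manifest <- list(package = "top2dsb",
                     version = as.character(utils::packageVersion("top2dsb")),
                     seed = config$seed,
                     parameters = par,
                     n_sites = length(sites),
                     samples = sheet$sample_id)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(quantified = quantified, persistence = persistence,
                   species = species, resection = resection,
                   stratified = stratified, sheet = sheet,
                   truth = dat$truth, sites = sites))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
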