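#' Configuration of the full error-analysis workflow
#'
#' One object drives the whole pipeline: simulate (or load) spectra, screen
#' gross outliers, apply each preprocessing variant, run ASCA with
#' permutation tests, estimate pooled error surfaces per sample, and
#' summarise them with the K index and image histograms.
#'
#' @param input either a [simConfig()] (simulated input) or a list
#'   `list(spectra = path, design = path)` naming a CSV pair for
#'   [readSpectraCSV()].
#' @param variants named list of preprocessing variants (see
#'   [applyPreprocess()]); default raw, SNV, and first-derivative
#'   Savitzky-Golay (window 7, polynomial order 2).
#' @param ascaFactors design factors for ASCA; default (`NULL`) uses every
#'   available factor among `replicate_order`, `session`,
#'   `background_timing`, `power_supply`.
#' @param interactions `"all"`, `"none"` or a list of pairs (see
#'   [ascaDecompose()]).
#' @param errorGrouping replicate-group factors for [errorMatrix()];
#'   default (`NULL`) groups by every factor except `replicate_order` and
#'   `instrument_config`.
#' @param nPerm permutation count for significance testing (default 2000).
#' @param outlierAlpha significance level of the gross-outlier limits.
#' @param seed root seed recorded in all outputs.
#' @param outputDir output directory.
#' @return a `WorkflowConfig` list.
#' @export
workflowConfig <- function(input,
                           variants = list(
                               none = "none",
                               snv = "snv",
                               first_derivative = list(
                                   step = "savgol", window = 7,
                                   polyorder = 2, derivorder = 1)),
                           ascaFactors = NULL,
                           interactions = "all",
                           errorGrouping = NULL,
                           nPerm = 2000,
                           outlierAlpha = 0.01,
                           seed = 1,
                           outputDir = "specerror-output") {
    if (length(variants) < 1L)
        stop("at least one preprocessing variant is required")
    if (is.null(names(variants)) || any(names(variants) == ""))
        stop("variants must be a named list")
    cfg <- list(input = input, variants = variants,
                ascaFactors = ascaFactors, interactions = interactions,
                errorGrouping = errorGrouping, nPerm = nPerm,
                outlierAlpha = outlierAlpha, seed = as.integer(seed),
                outputDir = outputDir)
    class(cfg) <- "WorkflowConfig"
    cfg
}

#' Read a workflow configuration from a YAML file
#'
#' @param path YAML file with the fields of [workflowConfig()]; the
#'   `input` field is either a `sim:` block of [simConfig()] arguments or
#'   a `csv:` block with `spectra:` and `design:` paths.
#' @return a `WorkflowConfig`.
#' @export
readWorkflowConfig <- function(path) {
    y <- yaml::read_yaml(path)
    input <- if (!is.null(y$input$sim)) do.call(simConfig, y$input$sim)
             else if (!is.null(y$input$csv)) y$input$csv
             else stop("config 'input' needs a 'sim' or 'csv' block")
    args <- y[setdiff(names(y), "input")]
    do.call(workflowConfig, c(list(input = input), args))
}

.writeMatrixCSV <- function(m, wl, path) {
    df <- as.data.frame(m)
    names(df) <- format(wl, trim = TRUE)
    utils::write.csv(cbind(wavelength = format(wl, trim = TRUE), df),
                     path, row.names = FALSE, quote = FALSE)
}

#' Run the full error-analysis workflow
#'
#' Executes simulate/load -> gross-outlier screening -> per-variant
#' preprocessing -> ASCA with permutation tests -> per-sample pooled error
#' surfaces -> K index and image histograms, writing CSV tables and a JSON
#' run manifest under `cfg$outputDir`. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param cfg a [workflowConfig()].
#' @return invisibly, a list with the K-index table (`kTable`), the ASCA
#'   tables (`asca`), the outlier flags and the manifest.
#' @export
runWorkflow <- function(cfg) {
    stopifnot(inherits(cfg, "WorkflowConfig"))
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    stage <- "input"
    result <- tryCatch({
        set.seed(cfg$seed)
        s <- if (inherits(cfg$input, "SimConfig"))
            simulateSpectra(buildDesign(cfg$input), cfg$input,
                            seed = cfg$seed)
        else readSpectraCSV(cfg$input$spectra, cfg$input$design)
        design <- designTable(s)

        stage <- "outlier screening"
        flags <- flagGrossOutliers(s, alpha = cfg$outlierAlpha)
        message("outlier screening: ", sum(flags), " of ", length(flags),
                " acquisitions flagged (flags reported, not dropped)")

        ascaFactors <- cfg$ascaFactors
        if (is.null(ascaFactors))
            ascaFactors <- intersect(
                c("replicate_order", "session", "background_timing",
                  "power_supply"), names(design))
        ascaFactors <- ascaFactors[vapply(ascaFactors, function(f)
            length(unique(design[[f]])) > 1L, logical(1))]
        samples <- if ("sample" %in% names(design))
            levels(factor(design$sample)) else "all"

        kTable <- NULL
        ascaTables <- list()
        files <- character()
        for (vn in names(cfg$variants)) {
            stage <- paste0("preprocess '", vn, "'")
            sv <- applyPreprocess(s, cfg$variants[[vn]])
            for (sm in samples) {
                cell <- paste0(vn, "/", sm)
                stage <- paste0("subset ", cell)
                ss <- if (identical(sm, "all")) sv else
                    subsetSpectra(sv, sample = sm)
                n <- ncol(ss)

                stage <- paste0("ASCA ", cell)
                dec <- ascaDecompose(ss, ascaFactors,
                                     interactions = cfg$interactions)
                tab <- ascaEffectTable(ss, dec, nPerm = cfg$nPerm,
                                       seed = cfg$seed)
                tab <- cbind(variant = vn, sample = sm, tab)
                ascaTables[[cell]] <- tab

                stage <- paste0("error surfaces ", cell)
                em <- errorMatrix(ss, replicateGroup = local({
                    eg <- cfg$errorGrouping
                    if (is.null(eg)) NULL else setdiff(eg, "sample")
                }))
                surf <- correlationMatrix(pooledCovariance(em))
                slug <- gsub("[^A-Za-z0-9]+", "_", cell)
                f1 <- file.path(cfg$outputDir,
                                paste0("sigma_cov_", slug, ".csv"))
                f2 <- file.path(cfg$outputDir,
                                paste0("sigma_cor_", slug, ".csv"))
                f3 <- file.path(cfg$outputDir,
                                paste0("variance_profile_", slug, ".csv"))
                .writeMatrixCSV(surf@sigmaCov, surf@wavelengths, f1)
                keep <- setdiff(seq_along(surf@wavelengths),
                                surf@excluded)
                .writeMatrixCSV(surf@sigmaCor, surf@wavelengths[keep], f2)
                utils::write.csv(varianceProfile(surf), f3,
                                 row.names = FALSE, quote = FALSE)
                files <- c(files, f1, f2, f3)

                stage <- paste0("K index ", cell)
                ki <- kIndex(surf@sigmaCor, rank = em@rankBound)
                hist <- imageHistogram(surf@sigmaCor)
                f4 <- file.path(cfg$outputDir,
                                paste0("histogram_", slug, ".csv"))
                utils::write.csv(data.frame(
                    bin_left = hist@breaks[-length(hist@breaks)],
                    bin_right = hist@breaks[-1],
                    count = hist@counts), f4, row.names = FALSE,
                    quote = FALSE)
                files <- c(files, f4)
                kTable <- rbind(kTable, data.frame(
                    sample = sm, variant = vn, n = n,
                    dof = surf@dof, k = ki@k, kMin = ki@kMin,
                    distance = ki@distance,
                    histMode = hist@mode, histSkewness = hist@skewness))
            }
            stage <- paste0("ASCA table '", vn, "'")
        }
        stage <- "report"
        ascaAll <- do.call(rbind, ascaTables)
        fA <- file.path(cfg$outputDir, "asca_effects.csv")
        utils::write.csv(ascaAll, fA, row.names = FALSE, quote = FALSE)
        fK <- file.path(cfg$outputDir, "k_index.csv")
        utils::write.csv(kTable, fK, row.names = FALSE, quote = FALSE)
        files <- c(files, fA, fK)

        cfgYaml <- file.path(cfg$outputDir, "config.yaml")
        yaml::write_yaml(.serializableConfig(cfg), cfgYaml)
        manifest <- list(
            package = "specerror",
            version = as.character(utils::packageVersion("specerror")),
            seed = cfg$seed,
            configHash = unname(tools::md5sum(cfgYaml)),
            nAcquisitions = ncol(s),
            nChannels = nrow(s),
            outliersFlagged = sum(flags),
            permutationScheme = paste("free permutation of the tested",
                                      "term's labels across rows"),
            files = basename(files))
        jsonlite::write_json(manifest,
                             file.path(cfg$outputDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        list(kTable = kTable, asca = ascaAll, outlierFlags = flags,
             manifest = manifest)
    }, error = function(e) {
        stop("workflow failed at stage [", stage, "]: ",
             conditionMessage(e), call. = FALSE)
    })
    invisible(result)
}

.serializableConfig <- function(cfg) {
    out <- unclass(cfg)
    if (inherits(out$input, "SimConfig"))
        out$input <- list(sim = unclass(out$input))
    else out$input <- list(csv = out$input)
    out
}
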