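#' Run the full ERV characterization pipeline
#'
#' Orchestrates the stages in order — element calling, type/subgroup/ORF
#' classification, age estimation (paired-LTR plus calibrated solo-consensus),
#' recombination detection, and chromosomal-distribution statistics — writing
#' one TSV per stage plus a JSON manifest recording parameters and inputs.
#' Stages already present on disk are skipped when `resume = TRUE`; a stage
#' failure aborts the run naming the stage, and downstream stages are not
#' run.
#'
#' The configuration is a nested list (or a YAML file with the same keys):
#' \describe{
#'   \item{input}{Either `simulate = TRUE` with a `sim` list of
#'     [simulationConfig()] arguments, or file paths `annotation` (+
#'     `dialect`), `genes`, `chromSizes`, `alignment`.}
#'   \item{stages}{Character subset of
#'     `c("call", "classify", "age", "recomb", "dist")` (default all).}
#'   \item{params}{Stage parameters: `minSoloLen` (750), `maxGap` (1000),
#'     `minGeneFraction` (0.5), `proximityWindow` (30000), `minLtrBases`
#'     (250), clock rates via [clockParameters()] arguments, `calibrate`
#'     (TRUE).}
#'   \item{seed}{Integer seed recorded in the manifest and used for any
#'     randomness.}
#' }
#'
#' @param config Nested list as above, or path to a YAML file.
#' @param outDir Output directory.
#' @param resume Skip stages whose outputs already exist (default FALSE).
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
runErvPipeline <- function(config, outDir, resume = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("call", "classify", "age", "recomb", "dist")
  params <- config$params %||% list()
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(seed = seed, stages = stages, params = params,
                   outputs = list(), warnings = list())

  ## ---- inputs ----
  sim <- NULL
  if (isTRUE(config$input$simulate)) {
    simArgs <- config$input$sim %||% list()
    simArgs$seed <- simArgs$seed %||% seed
    simCfg <- do.call(simulationConfig, simArgs)
    sim <- simulateCatalog(simCfg)
    hits <- sim$hits; genes <- sim$genes
    chromSizes <- sim$chromSizes
    aln <- sim$provirusAlignment
    frame <- sim$frame
    manifest$input <- list(simulate = TRUE, sim_seed = simCfg@seed)
  } else {
    hits <- readRepeatAnnotation(config$input$annotation,
                                 dialect = config$input$dialect %||% "bed_tsv")
    genes <- .readGenesBed(config$input$genes)
    chromSizes <- read.delim(config$input$chromSizes, header = FALSE,
                             col.names = c("chrom", "length"),
                             stringsAsFactors = FALSE)
    aln <- if (!is.null(config$input$alignment)) {
      readAlignedFasta(config$input$alignment, reference = config$input$reference)
    } else NULL
    frame <- config$input$frame
    manifest$input <- list(simulate = FALSE,
                           files = unlist(config$input[c("annotation", "genes", "chromSizes", "alignment")]))
  }

  runStage <- function(name, outFiles, fun) {
    if (!(name %in% stages)) return(NULL)
    paths <- file.path(outDir, outFiles)
    if (resume && all(file.exists(paths))) {
      manifest$outputs[[name]] <<- outFiles
      return(NULL)
    }
    res <- tryCatch(fun(paths), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$outputs[[name]] <<- outFiles
    res
  }

  catalog <- NULL
  runStage("call", "catalog.tsv", function(paths) {
    prov <- callProviruses(hits, maxGap = params$maxGap %||% 1000,
                           minGeneFraction = params$minGeneFraction %||% 0.5)
    solo <- callSoloLtrs(hits, prov, minLen = params$minSoloLen %||% 750,
                         exclusionWindow = params$maxGap %||% 1000)
    catalog <<- ErvCatalog(rbind(as.data.frame(prov), as.data.frame(solo)))
    writeCatalog(catalog, paths[1L])
  })
  if (is.null(catalog) && file.exists(file.path(outDir, "catalog.tsv"))) {
    catalog <- readCatalog(file.path(outDir, "catalog.tsv"))
  }

  ## classification, ages and recombination need the alignment + frame
  clock <- do.call(clockParameters, params$clock %||% list())
  provIds <- if (!is.null(sim)) {
    sim$truth$element_id[sim$truth$kind == "provirus"]
  } else if (!is.null(aln)) setdiff(alignmentNames(aln), referenceName(aln)) else character(0)

  runStage("classify", c("types.tsv", "subgroups.tsv", "orfs.tsv"), function(paths) {
    if (is.null(aln) || is.null(frame)) stop("classification requires an alignment and frame info")
    win <- frame$deletionWindow
    types <- do.call(rbind, lapply(provIds, function(id) {
      tc <- classifyType(aln, id, window = win)
      data.frame(element_id = id, type = tc$call,
                 fraction_deleted = tc$fractionDeleted, stringsAsFactors = FALSE)
    }))
    write.table(types, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    diag <- frame$provirusDiagnostics
    subs <- do.call(rbind, lapply(provIds, function(id) {
      sc <- classifySubgroup(alignmentRow(aln, id), diag)
      data.frame(element_id = id, subgroup = sc$subgroup,
                 hs_present = sc$hsPresent, ab_present = sc$abPresent,
                 a_present = sc$aPresent, stringsAsFactors = FALSE)
    }))
    write.table(subs, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    orfs <- do.call(rbind, lapply(provIds, function(id) {
      callOrfs(aln, id, regions = frame$regionMap)
    }))
    write.table(orfs, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  })

  runStage("age", "ages.tsv", function(paths) {
    if (is.null(aln) || is.null(frame)) stop("age estimation requires an alignment and frame info")
    ages <- .ageStage(aln, frame, provIds, clock, sim, params)
    write.table(ages, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  })

  runStage("recomb", "ltr_pairing.tsv", function(paths) {
    if (is.null(aln) || is.null(frame)) stop("recombination detection requires an alignment and frame info")
    pairing <- .pairingTable(aln, frame, provIds, params)
    write.table(pairing, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  })

  runStage("dist", c("regression.tsv", "proximity.tsv"), function(paths) {
    if (is.null(catalog)) stop("distribution stage requires the catalog stage output")
    summ <- chromosomeSummary(catalog, genes, chromSizes)
    reg <- fitAllNbRegressions(summ)
    write.table(reg, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    prox <- geneProximitySummary(catalog, genes,
                                 window = params$proximityWindow %||% 30000)
    write.table(data.frame(metric = c("n_total", "n_within_window", "n_intronic",
                                      "n_intronic_antisense"),
                           value = c(prox$nTotal, prox$nWithinWindow,
                                     prox$nIntronic, prox$nIntronicAntisense)),
                paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest$package_version <- as.character(utils::packageVersion("ervatlas"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.readGenesBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start0", "end", "name", "score", "strand")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start0 + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = df$name, feature = "gene")
  gr
}

## extract the cognate LTR rows of each provirus into the single-LTR frame
.ltrRows <- function(aln, frame, provIds) {
  l5 <- extractRegion(aln, cols = frame$ltr5Cols)
  l3 <- extractRegion(aln, cols = frame$ltr3Cols)
  rows <- c(
    stats::setNames(lapply(provIds, function(id) alignmentRow(l5, id)),
                    paste0(provIds, "_5LTR")),
    stats::setNames(lapply(provIds, function(id) alignmentRow(l3, id)),
                    paste0(provIds, "_3LTR")))
  vapply(rows, identity, character(1))
}

.ageStage <- function(aln, frame, provIds, clock, sim, params) {
  ltr <- .ltrRows(aln, frame, provIds)
  paired <- lapply(provIds, function(id) {
    dv <- tryCatch(countDivergence(ltr[paste0(id, "_5LTR")], ltr[paste0(id, "_3LTR")]),
                   error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    est <- estimateProvirusAge(dv, clock, elementId = id)
    data.frame(element_id = id, method = est$method, age_low = est$ageLow,
               age_point = est$agePoint, age_high = est$ageHigh,
               young_flag = est$youngFlag, stringsAsFactors = FALSE)
  })
  paired <- do.call(rbind, paired[!vapply(paired, is.null, logical(1))])
  ## solo-consensus ages for solo LTRs (when a solo alignment is simulated)
  solo <- NULL
  if (!is.null(sim)) {
    soloAln <- sim$soloAlignment
    soloIds <- setdiff(alignmentNames(soloAln), referenceName(soloAln))
    diag <- frame$soloDiagnostics
    sg <- vapply(soloIds, function(id) classifySubgroup(alignmentRow(soloAln, id), diag)$subgroup,
                 character(1))
    cons <- lapply(split(soloIds, sg), function(ids) buildConsensus(soloAln, ids))
    if (isTRUE(params$calibrate %||% TRUE) && nrow(paired) >= 3L) {
      ## consensus-method ages of the 2-LTR proviruses' 5' LTRs
      sg5 <- vapply(provIds, function(id) classifySubgroup(ltr[paste0(id, "_5LTR")],
                                                           frame$soloDiagnostics)$subgroup,
                    character(1))
      consAges <- vapply(seq_along(provIds), function(i) {
        cc <- cons[[sg5[i]]]
        if (is.null(cc)) return(NA_real_)
        tryCatch(estimateSoloAge(ltr[paste0(provIds[i], "_5LTR")], cc, clock)$agePoint,
                 error = function(e) NA_real_)
      }, numeric(1))
      pairedPoint <- paired$age_point[match(provIds, paired$element_id)]
      ok <- is.finite(consAges) & is.finite(pairedPoint)
      if (sum(ok) >= 3L) {
        cal <- calibrateCorrectionFactor(consAges[ok], pairedPoint[ok])
        clock <- applyCalibration(clock, cal)
      }
    }
    solo <- do.call(rbind, lapply(seq_along(soloIds), function(i) {
      cc <- cons[[sg[i]]]
      if (is.null(cc)) return(NULL)
      est <- tryCatch(estimateSoloAge(alignmentRow(soloAln, soloIds[i]), cc, clock,
                                      elementId = soloIds[i]),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      data.frame(element_id = soloIds[i], method = est$method, age_low = est$ageLow,
                 age_point = est$agePoint, age_high = est$ageHigh,
                 young_flag = est$youngFlag, stringsAsFactors = FALSE)
    }))
  }
  rbind(paired, solo)
}

.pairingTable <- function(aln, frame, provIds, params) {
  ltr <- .ltrRows(aln, frame, provIds)
  ltrAln <- ErvAlignment(ltr, reference = names(ltr)[1L])
  dm <- suppressWarnings(ltrDistanceMatrix(ltrAln, names = names(ltr),
                                           minBases = params$minLtrBases %||% 250L))
  pairing <- data.frame(provirus_id = provIds,
                        ltr5 = paste0(provIds, "_5LTR"),
                        ltr3 = paste0(provIds, "_3LTR"),
                        stringsAsFactors = FALSE)
  tree <- if (nrow(dm) >= 3L && !anyNA(dm)) buildNjTree(dm) else NULL
  suppressWarnings(detectUnpairedLtrs(dm, pairing, tree = tree))
}
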