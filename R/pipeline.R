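## pipeline: orchestrate simulate/ingest -> extinction series ->
## beta-diversity -> function response -> per-level networks under one
## config, with a deterministic report bundle.

#' Configure an end-to-end analysis run
#'
#' @param input a [LinkedProfile-class], a [SyntheticConfig-class] (the
#'   community is generated at run time), or a path to a profile TSV.
#' @param levelSizes strictly decreasing retained-phylum counts; `NULL`
#'   (default) uses the full count then 8, 5, 2, 1 where available.
#' @param nPermutations permutations for every PERMANOVA stage.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param dominanceCutoff,panelCutoff dominance cutoffs for the level-1
#'   trend report (default 1%) and the function-specific statistic panel
#'   (default 0.5%).
#' @param network a [NetworkConfig-class] used for every per-level network.
#' @param networkLevels which tables get networks: taxonomy at genus and
#'   function at level 3 by default.
#' @param outDir output directory for the report bundle.
#' @return a list of class `funlossRunConfig`.
#' @export
runConfig <- function(input, levelSizes = NULL, nPermutations = 999,
                      seed = 1, dominanceCutoff = 0.01, panelCutoff = 0.005,
                      network = networkConfig(),
                      networkLevels = c(taxonomy = "genus",
                                        `function` = "level3"),
                      outDir = "funloss_run") {
  stopifnot(is(network, "NetworkConfig"))
  structure(list(input = input, levelSizes = levelSizes,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed),
                 dominanceCutoff = dominanceCutoff,
                 panelCutoff = panelCutoff, network = network,
                 networkLevels = networkLevels, outDir = outDir),
            class = "funlossRunConfig")
}

resolveInput <- function(input) {
  if (is(input, "LinkedProfile")) input
  else if (is(input, "SyntheticConfig")) generateCommunity(input)
  else if (is.character(input) && length(input) == 1) readLinkedProfile(input)
  else stop("input must be a LinkedProfile, SyntheticConfig or file path")
}

writeReportTable <- function(df, path, stage, params) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# stage: ", stage), paste0("# params: ", params)), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Stack per-level loss-series tables into the one-factor design
#'
#' Concatenates the per-level relative-abundance tables of a
#' [lossSeries()] report into one samples x features matrix whose rows are
#' `"<sample>@<level>"`, with the loss level as the single grouping factor
#' -- the design the loss-level PERMANOVA runs on. All-zero rows (samples
#' that lost every hit at a level) are dropped.
#'
#' @param report a [LossSeriesReport-class].
#' @param which `"taxonomyRelative"` (genus-level) or `"funcRelative"`
#'   (function-level).
#' @return list with `x` (matrix) and `groups` (factor of level names).
#' @export
stackLevels <- function(report, which = c("taxonomyRelative", "funcRelative")) {
  which <- match.arg(which)
  mats <- lapply(names(report@tables), function(lv) {
    m <- asMatrixInput(report@tables[[lv]][[which]])
    rownames(m) <- paste(rownames(m), lv, sep = "@")
    m
  })
  features <- sort(unique(unlist(lapply(mats, colnames))))
  full <- lapply(mats, function(m) {
    out <- matrix(0, nrow(m), length(features),
                  dimnames = list(rownames(m), features))
    out[, colnames(m)] <- m
    out
  })
  x <- do.call(rbind, full)
  groups <- factor(rep(names(report@tables),
                       vapply(full, nrow, integer(1))),
                   levels = names(report@tables))
  keep <- rowSums(x) > 0
  list(x = x[keep, , drop = FALSE], groups = droplevels(groups[keep]))
}

#' Run the full directed-loss analysis and write the report bundle
#'
#' Stages: resolve or generate the input profile; rank phyla and build the
#' nested loss levels; run the loss series (S/N report); concatenate the
#' per-level relative-abundance tables into the one-factor design; run
#' Bray-Curtis + PCoA + PERMANOVA main and pairwise tests for taxonomy
#' (genus level) and function (function level); run the function-response
#' panel (level-1 trends, per-category ANOVA, within-category renormalized
#' PERMANOVA, abundance-response correlation, Spearman/UPGMA heatmap); build
#' per-level co-occurrence networks for taxonomy (genus) and function
#' (level 3); write every table with a stage/parameter comment header plus a
#' machine-readable manifest. Two runs with an identical config are
#' byte-identical.
#'
#' @param config a [runConfig()] list.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with every in-memory result (`profile`,
#'   `ranking`, `levels`, `lossReport`, `betadiv`, `functionResponse`,
#'   `networks`, `manifest`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "funlossRunConfig"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  say("stage ingest: resolving input profile")
  profile <- resolveInput(config$input)
  say(sprintf("  %d samples, %d records",
              length(sampleIds(profile)), nrow(profileRecords(profile))))

  say("stage extinction: ranking phyla and building loss levels")
  ranking <- rankPhyla(profile)
  levels_ <- defaultLevels(ranking, config$levelSizes)
  report <- lossSeries(profile, levels_)
  lossTab <- report@summary
  for (nm in names(report@correlations)) {
    cr <- report@correlations[[nm]]
    lossTab[[paste0("r2_", nm)]] <- cr@r2
  }
  writeReportTable(lossTab, file.path(config$outDir, "loss_report.tsv"),
                   "extinction",
                   sprintf("levels=%s",
                           paste(vapply(levels_, function(l) l@name,
                                        character(1)), collapse = ",")))

  betares <- list()
  for (kind in c("taxonomy", "function")) {
    slot_ <- if (kind == "taxonomy") "taxonomyRelative" else "funcRelative"
    say(sprintf("stage betadiv (%s): Bray-Curtis, PCoA, PERMANOVA", kind))
    st <- stackLevels(report, slot_)
    if (nlevels(st$groups) < 2 || any(table(st$groups) < 2)) {
      say("  skipped: fewer than two usable groups")
      next
    }
    d <- suppressMessages(brayCurtis(st$x, relative = FALSE))
    ord <- pcoa(d, nAxes = 2)
    main <- permanova(d, st$groups, config$nPermutations,
                      seed = config$seed + 101L)
    pw <- permanovaPairwise(d, st$groups, config$nPermutations,
                            seed = config$seed + 201L)
    simPct <- meanSimilarityPct(d)
    betares[[kind]] <- list(dist = d, pcoa = ord, main = main, pairwise = pw,
                            meanSimilarityPct = simPct)
    mainTab <- data.frame(kind = kind, pseudo_F = main@pseudoF,
                          df_between = main@dfBetween,
                          df_within = main@dfWithin, R2 = main@R2,
                          p = main@p, mean_similarity_pct = simPct)
    prm <- sprintf("permutations=%d seed=%d", config$nPermutations,
                   config$seed)
    writeReportTable(rbind(mainTab),
                     file.path(config$outDir,
                               sprintf("permanova_%s.tsv", kind)),
                     "betadiv", prm)
    writeReportTable(pw, file.path(config$outDir,
                                   sprintf("pairwise_%s.tsv", kind)),
                     "betadiv", prm)
    coords <- data.frame(sample = rownames(ord@coordinates),
                         ord@coordinates,
                         percent_variation_1 = ord@percentVariation[1],
                         percent_variation_2 = ord@percentVariation[2])
    writeReportTable(coords, file.path(config$outDir,
                                       sprintf("pcoa_%s.tsv", kind)),
                     "betadiv", prm)
  }

  say("stage function_response: category trends and statistics")
  l1tables <- lapply(names(report@tables), function(lv) {
    filtered <- suppressWarnings(applyLossLevel(profile,
      levels_[[match(lv, vapply(levels_, function(l) l@name, character(1)))]]))
    suppressWarnings(toRelativeAbundance(
      projectProfile(filtered, "function", "level1")))
  })
  names(l1tables) <- names(report@tables)
  trends <- categoryTrends(l1tables, config$dominanceCutoff)
  funcResp <- list(trends = trends)
  stf <- stackLevels(report, "funcRelative")
  if (nlevels(stf$groups) >= 2 && all(table(stf$groups) >= 2)) {
    fm <- functionMap(profile)
    lineage <- data.frame(function_id = rownames(fm), level1 = fm$level1,
                          stringsAsFactors = FALSE)
    l1stack <- lapply(names(l1tables), function(lv) {
      m <- asMatrixInput(l1tables[[lv]])
      rownames(m) <- paste(rownames(m), lv, sep = "@")
      m
    })
    cats <- sort(unique(unlist(lapply(l1stack, colnames))))
    l1x <- do.call(rbind, lapply(l1stack, function(m) {
      out <- matrix(0, nrow(m), length(cats),
                    dimnames = list(rownames(m), cats))
      out[, colnames(m)] <- m
      out
    }))
    l1x <- l1x[rownames(stf$x), , drop = FALSE]
    aov_tab <- anovaPerCategory(l1x, stf$groups)
    wperm <- withinCategoryPermanova(stf$x, lineage, stf$groups,
                                     config$nPermutations,
                                     seed = config$seed + 301L)
    panel <- merge(trends[c("category", "overall_mean", "dominant")],
                   merge(aov_tab[c("category", "F", "p")], wperm,
                         by = "category", all = TRUE),
                   by = "category", all = TRUE)
    names(panel)[names(panel) == "p.x"] <- "anova_p"
    names(panel)[names(panel) == "p.y"] <- "permanova_p"
    panel <- panel[order(-panel$overall_mean), ]
    dom <- panel[!is.na(panel$overall_mean) &
                 panel$overall_mean > config$panelCutoff, ]
    corRes <- NULL
    if (sum(stats::complete.cases(dom[c("overall_mean", "pseudo_F")])) >= 3)
      corRes <- abundanceResponseCorrelation(
        setNames(dom$overall_mean, dom$category),
        setNames(dom$pseudo_F, dom$category))
    funcResp$panel <- panel
    funcResp$abundanceResponse <- corRes
    writeReportTable(panel,
                     file.path(config$outDir, "category_response.tsv"),
                     "function_response",
                     sprintf("dominance=%g panel=%g permutations=%d",
                             config$dominanceCutoff, config$panelCutoff,
                             config$nPermutations))
  }
  meanCols <- grep("^mean_", names(trends), value = TRUE)
  hm_in <- as.matrix(trends[trends$dominant, meanCols, drop = FALSE])
  rownames(hm_in) <- trends$category[trends$dominant]
  if (nrow(hm_in) >= 2 && ncol(hm_in) >= 2) {
    hm <- suppressMessages(heatmapCluster(hm_in))
    funcResp$heatmap <- hm
    zdf <- data.frame(category = rownames(hm@matrix), hm@matrix,
                      leaf_position = match(seq_len(nrow(hm@matrix)),
                                            hm@rowOrder),
                      check.names = FALSE)
    writeReportTable(zdf, file.path(config$outDir, "heatmap_matrix.tsv"),
                     "function_response", "zscore rows, spearman+UPGMA")
    mg <- hm@linkage$merge
    linkTab <- data.frame(step = seq_len(nrow(mg)), left = mg[, 1],
                          right = mg[, 2], height = hm@linkage$height)
    writeReportTable(linkTab, file.path(config$outDir, "linkage.tsv"),
                     "function_response", "UPGMA merge history")
  }

  say("stage network: per-level co-occurrence networks")
  networks <- list()
  idxRows <- list()
  for (kind in names(config$networkLevels)) {
    lvl <- config$networkLevels[[kind]]
    for (ln in names(report@tables)) {
      filtered <- suppressWarnings(applyLossLevel(profile,
        levels_[[match(ln, vapply(levels_, function(l) l@name,
                                  character(1)))]]))
      tab <- suppressWarnings(toRelativeAbundance(
        projectProfile(filtered, kind, lvl)))
      key <- sprintf("%s_%s", kind, ln)
      net <- tryCatch({
        prep <- prepareMatrix(tab, config$network)
        corr <- suppressWarnings(correlationMatrix(prep))
        st <- selectThreshold(corr, config$network)
        cls <- if (kind == "taxonomy") taxonomyMap(profile)
               else setNames(functionMap(profile)$level1,
                             rownames(functionMap(profile)))
        suppressWarnings(buildNetwork(corr, st, cls))
      }, error = function(e) {
        say(sprintf("  network %s skipped: %s", key, conditionMessage(e)))
        NULL
      })
      if (is.null(net)) next
      networks[[key]] <- net
      exportCytoscape(net, file.path(config$outDir, "networks", key))
      idxRows[[key]] <- data.frame(kind = kind, level = ln, st = net@st,
                                   t(net@indexes),
                                   n_components = net@nComponents)
    }
  }
  if (length(idxRows))
    writeReportTable(do.call(rbind, idxRows),
                     file.path(config$outDir, "network_indexes.tsv"),
                     "network",
                     sprintf("method=%s prevalence>%g fill=%g",
                             config$network@thresholdMethod,
                             config$network@prevalenceMin,
                             config$network@fillValue))

  manifest <- list(
    package = "funloss",
    version = as.character(utils::packageVersion("funloss")),
    seed = config$seed,
    permutations = config$nPermutations,
    level_sizes = vapply(levels_, function(l) length(l@retainedPhyla),
                         integer(1)),
    config_hash = configHash(config),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(profile = profile, ranking = ranking, levels = levels_,
                 lossReport = report, betadiv = betares,
                 functionResponse = funcResp, networks = networks,
                 manifest = manifest))
}

## Stable hash of the run configuration: serialize deterministically to a
## temp file and md5 it.
configHash <- function(config) {
  cfg <- config
  cfg$outDir <- NULL
  if (is(cfg$input, "LinkedProfile"))
    cfg$input <- list("LinkedProfile",
                      nrow(profileRecords(cfg$input)),
                      sum(profileRecords(cfg$input)$hits))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(cfg, con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}
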