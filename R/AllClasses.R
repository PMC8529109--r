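#' @import methods
#' @importFrom data.table data.table as.data.table fread fwrite setnames
#'   setcolorder setorderv
#' @importFrom stats anova as.dist complete.cases cor dist hclust lm
#'   p.adjust pt rgamma rlnorm rpois sd setNames var
NULL

REQUIRED_COLUMNS <- c("sample", "genus", "phylum", "function_id",
                      "level1", "level2", "level3", "hits")

#' Joint taxonomy-by-function profile
#'
#' A `LinkedProfile` holds per-sample annotation hit counts indexed jointly by
#' genus (with its phylum) and function (with its three-level Subsystems-style
#' lineage). The joint key is what makes taxonomy-filtered functional profiles
#' possible: removing a phylum removes the functional hits its genera carried.
#'
#' @slot records data.frame with columns `sample`, `genus`, `phylum`,
#'   `function_id`, `level1`, `level2`, `level3`, `hits`; one row per unique
#'   (sample, genus, function_id) key; `hits` non-negative.
#' @slot samples character vector of sample identifiers in their original
#'   order; every `records$sample` occurs here.
#' @slot taxonomyMap named character vector mapping genus -> phylum.
#' @slot functionMap data.frame keyed by rowname `function_id` with columns
#'   `level3`, `level2`, `level1`.
#'
#' @seealso [readLinkedProfile()], [generateCommunity()], [projectProfile()]
#' @export
setClass("LinkedProfile",
  slots = c(records = "data.frame",
            samples = "character",
            taxonomyMap = "character",
            functionMap = "data.frame"))

setValidity("LinkedProfile", function(object) {
  rec <- object@records
  msgs <- character()
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(rec))
  if (length(missing_cols))
    return(sprintf("records lack column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (nrow(rec)) {
    if (any(is.na(rec$hits)) || any(rec$hits < 0))
      msgs <- c(msgs, "hits must be non-negative and non-missing")
    key <- paste(rec$sample, rec$genus, rec$function_id, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (sample, genus, function_id) keys")
    if (!all(rec$genus %in% names(object@taxonomyMap)))
      msgs <- c(msgs, "genus present in records but absent from taxonomyMap")
    if (!all(rec$function_id %in% rownames(object@functionMap)))
      msgs <- c(msgs, "function_id present in records but absent from functionMap")
    if (!all(rec$sample %in% object@samples))
      msgs <- c(msgs, "record sample not listed in samples slot")
  }
  if (anyDuplicated(object@samples))
    msgs <- c(msgs, "sample identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Sample-by-feature abundance table
#'
#' An `AbundanceTable` is a numeric matrix with samples in rows and features
#' (genera, phyla, or function categories at one hierarchy level) in columns,
#' plus the projection metadata saying what the features are. It extends base
#' `matrix`, so all matrix operations apply.
#'
#' @slot kind either `"taxonomy"` or `"function"`.
#' @slot level the hierarchy level the columns live at (`"phylum"`/`"genus"`
#'   for taxonomy; `"level1"`/`"level2"`/`"level3"`/`"function"` for function).
#' @slot relative logical; `TRUE` after [toRelativeAbundance()].
#'
#' @export
setClass("AbundanceTable",
  contains = "matrix",
  slots = c(kind = "character", level = "character", relative = "logical"),
  prototype = prototype(kind = "taxonomy", level = "genus", relative = FALSE))

setValidity("AbundanceTable", function(object) {
  msgs <- character()
  if (!object@kind %in% c("taxonomy", "function"))
    msgs <- c(msgs, "kind must be 'taxonomy' or 'function'")
  if (length(object) && (any(is.na(object@.Data)) || any(object@.Data < 0)))
    msgs <- c(msgs, "abundance values must be non-negative and non-missing")
  if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
    msgs <- c(msgs, "feature ids must be unique")
  if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
    msgs <- c(msgs, "sample ids must be unique")
  if (object@relative && nrow(object)) {
    rs <- rowSums(object@.Data)
    if (any(abs(rs - 1) > 1e-9 & rs > 0))
      msgs <- c(msgs, "relative-abundance rows must sum to 1 or be all zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' One step of directed extinction: a named phylum retention set
#'
#' @slot name label for the step, conventionally the number of phyla retained
#'   (e.g. "All", "Eight", "Five", "Two", "One").
#' @slot retainedPhyla non-empty character vector of phylum names kept.
#' @export
setClass("LossLevel",
  slots = c(name = "character", retainedPhyla = "character"))

setValidity("LossLevel", function(object) {
  if (length(object@retainedPhyla) == 0)
    "retainedPhyla must be non-empty"
  else if (length(object@name) != 1 || is.na(object@name) || !nzchar(object@name))
    "name must be a single non-empty string"
  else TRUE
})

#' Configuration of the synthetic community generator
#'
#' See [syntheticConfig()] for field meanings and defaults.
#' @export
setClass("SyntheticConfig",
  slots = c(nSamples = "integer", nPhyla = "integer",
            generaPerPhylum = "integer", nFunctions = "integer",
            redundancy = "numeric", phylumDecay = "numeric",
            depth = "numeric", dispersion = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  counts <- c(nSamples = object@nSamples, nPhyla = object@nPhyla,
              generaPerPhylum = object@generaPerPhylum,
              nFunctions = object@nFunctions)
  if (any(counts < 1L))
    msgs <- c(msgs, sprintf("%s must be >= 1",
                            paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@redundancy < 0 || object@redundancy > 1)
    msgs <- c(msgs, "redundancy must lie in [0, 1]")
  if (object@phylumDecay <= 0 || object@phylumDecay >= 1)
    msgs <- c(msgs, "phylumDecay must lie in (0, 1)")
  if (object@dispersion < 0)
    msgs <- c(msgs, "dispersion must be >= 0")
  if (object@depth <= 0)
    msgs <- c(msgs, "depth must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the co-occurrence network pipeline
#'
#' See [networkConfig()] for field meanings and defaults.
#' @export
setClass("NetworkConfig",
  slots = c(prevalenceMin = "numeric", fillValue = "numeric",
            logBase = "numeric", thresholdMethod = "character",
            st = "numeric", scanRange = "numeric"))

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  if (!object@thresholdMethod %in% c("fixed", "scan"))
    msgs <- c(msgs, "thresholdMethod must be 'fixed' or 'scan'")
  if (object@st <= 0 || object@st >= 1)
    msgs <- c(msgs, "st must lie in (0, 1)")
  if (is.unsorted(object@scanRange, strictly = TRUE))
    msgs <- c(msgs, "scanRange must be strictly ascending")
  if (object@prevalenceMin < 0 || object@prevalenceMin >= 1)
    msgs <- c(msgs, "prevalenceMin must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Community richness and size summary
#'
#' @slot S species count: features whose pooled (across-sample) hits exceed 0.
#' @slot N individuals: the grand total of hits.
#' @export
setClass("CommunitySummary", slots = c(S = "numeric", N = "numeric"))

setValidity("CommunitySummary", function(object) {
  if (object@S < 0 || object@N < 0)
    "S and N must be non-negative"
  else if ((object@S == 0) != (object@N == 0))
    "S = 0 if and only if N = 0"
  else TRUE
})

# ---- result containers -----------------------------------------------------

#' Principal coordinates analysis result
#'
#' @slot coordinates samples x axes score matrix (axes ordered by descending
#'   eigenvalue, sign fixed so the largest-magnitude loading per axis is
#'   positive).
#' @slot eigenvalues all eigenvalues, descending; negative ones retained.
#' @slot percentVariation percent of variation per returned axis, computed
#'   over positive eigenvalues only.
#' @export
setClass("PcoaResult",
  slots = c(coordinates = "matrix", eigenvalues = "numeric",
            percentVariation = "numeric"))

#' PERMANOVA main-test result
#'
#' @slot pseudoF the pseudo-F statistic.
#' @slot dfBetween,dfWithin degrees of freedom (a - 1 and N - a).
#' @slot p permutation p-value, (1 + b) / (1 + m) estimator.
#' @slot R2 fraction of total sum of squares between groups.
#' @slot nPermutations,seed the Monte-Carlo settings used.
#' @export
setClass("PermanovaResult",
  slots = c(pseudoF = "numeric", dfBetween = "numeric", dfWithin = "numeric",
            p = "numeric", R2 = "numeric", nPermutations = "numeric",
            seed = "numeric"))

#' Pearson correlation result
#'
#' @slot r product-moment correlation; @slot r2 its square;
#' @slot p two-sided p from the t approximation; @slot n sample size.
#' @export
setClass("CorrelationResult",
  slots = c(r = "numeric", r2 = "numeric", p = "numeric", n = "numeric"))

#' Signed co-occurrence network with its index panel
#'
#' @slot nodes data.frame (`id`, `classification`, `module`, `degree`),
#'   lexicographic by id; only edge endpoints are nodes.
#' @slot edges data.frame (`source`, `target`, `sign`, `correlation`),
#'   undirected, source < target, lexicographic.
#' @slot indexes named numeric vector: `total_nodes`, `total_links`,
#'   `avg_connectivity`, `avg_clustering_coefficient`,
#'   `avg_geodesic_distance`, `modularity`, `pct_negative_links`.
#' @slot nComponents number of connected components.
#' @slot st similarity threshold the network was built at.
#' @export
setClass("NetworkResult",
  slots = c(nodes = "data.frame", edges = "data.frame",
            indexes = "numeric", nComponents = "numeric", st = "numeric"))

#' Heatmap clustering result
#'
#' @slot matrix categories x loss-levels matrix of per-row z-scores.
#' @slot rowOrder dendrogram leaf order (row indices of `matrix`).
#' @slot linkage the `hclust` merge history (UPGMA on Spearman distance).
#' @slot constantRows names of rows with zero variance (assigned maximal
#'   Spearman distance 2 to all others).
#' @export
setClass("HeatmapResult",
  slots = c(matrix = "matrix", rowOrder = "integer", linkage = "ANY",
            constantRows = "character"))

#' Loss-series report
#'
#' @slot summary data.frame with one row per (level, kind): S, N, and percent
#'   reductions relative to the full community.
#' @slot tables named list, one entry per level, each holding the genus-level
#'   taxonomy table and function-level function table (counts and relative
#'   abundance).
#' @slot correlations named list of [CorrelationResult-class] objects for S
#'   and N against level index, per kind.
#' @export
setClass("LossSeriesReport",
  slots = c(summary = "data.frame", tables = "list", correlations = "list"))
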