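## io_profiles: read/write joint taxonomy x function tables, project them to
## one-level abundance tables, and standardize to relative abundance.

UNCLASSIFIED_TAXON <- "unclassified_taxon"
UNCLASSIFIED_FUNCTION <- "unclassified_function"

TAXONOMY_LEVELS <- c("phylum", "genus")
FUNCTION_LEVELS <- c("level1", "level2", "level3", "function")

#' Construct a LinkedProfile from long-format records
#'
#' Duplicate (sample, genus, function_id) rows are summed; zero-hit rows are
#' kept out of the record set but their samples stay in `sampleIds()`.
#'
#' @param records data.frame with columns `sample`, `genus`, `phylum`,
#'   `function_id`, `level1`, `level2`, `level3`, `hits`.
#' @param samples optional sample ordering; defaults to first appearance.
#' @return a validated [LinkedProfile-class].
#' @export
linkedProfile <- function(records, samples = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[REQUIRED_COLUMNS]
  for (col in setdiff(REQUIRED_COLUMNS, "hits"))
    records[[col]] <- as.character(records[[col]])
  records$hits <- as.numeric(records$hits)
  if (anyNA(records$hits) || any(records$hits < 0)) {
    bad <- which(is.na(records$hits) | records$hits < 0)[1]
    stop("hits must be non-negative numbers; offending row ", bad)
  }
  if (nrow(records)) {
    blank <- function(x) is.na(x) | !nzchar(x)
    for (col in c("phylum", "genus", "function_id", "level1", "level2",
                  "level3", "sample")) {
      if (any(blank(records[[col]]))) {
        bad <- which(blank(records[[col]]))[1]
        stop(sprintf("column '%s' is empty at row %d", col, bad))
      }
    }
    conflicts <- unique(records[c("genus", "phylum")])
    dup <- conflicts$genus[duplicated(conflicts$genus)]
    if (length(dup))
      stop("genus mapped to more than one phylum: ",
           paste(unique(dup), collapse = ", "))
    fconf <- unique(records[c("function_id", "level3", "level2", "level1")])
    fdup <- fconf$function_id[duplicated(fconf$function_id)]
    if (length(fdup))
      stop("function_id mapped to more than one lineage: ",
           paste(unique(fdup), collapse = ", "))
  }
  if (is.null(samples)) samples <- unique(records$sample)
  dt <- data.table::as.data.table(records)
  dt <- dt[, list(hits = sum(hits)),
           by = c("sample", "genus", "phylum", "function_id",
                  "level1", "level2", "level3")]
  dt <- dt[dt$hits > 0, ]
  data.table::setcolorder(dt, REQUIRED_COLUMNS)
  data.table::setorderv(dt, c("sample", "genus", "function_id"))
  rec <- as.data.frame(dt)
  tax <- unique(rec[c("genus", "phylum")])
  taxonomy_map <- setNames(tax$phylum, tax$genus)
  fmap <- unique(rec[c("function_id", "level3", "level2", "level1")])
  rownames(fmap) <- fmap$function_id
  fmap$function_id <- NULL
  new("LinkedProfile", records = rec, samples = as.character(samples),
      taxonomyMap = taxonomy_map, functionMap = fmap)
}

#' Read a joint taxonomy x function profile from tab-separated text
#'
#' Reads long-format exports with one (sample, genus, function) record per
#' row, as produced by MG-RAST-style analysis downloads. Duplicate keys are
#' summed; row order never affects the result.
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @param dialect named character vector mapping canonical column names
#'   (`sample`, `genus`, `phylum`, `function_id`, `level1`, `level2`,
#'   `level3`, `hits`) to the file's header names. Unmapped names are taken
#'   as-is.
#' @param dropUnclassified if `TRUE`, records whose genus or function carries
#'   the unclassified sentinel are dropped; by default they are kept so hit
#'   totals are conserved.
#' @return a validated [LinkedProfile-class].
#' @export
readLinkedProfile <- function(path, dialect = character(),
                              dropUnclassified = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = TRUE, encoding = "UTF-8")
  for (canonical in names(dialect)) {
    if (!dialect[[canonical]] %in% names(raw))
      stop(sprintf("missing required column: '%s' (mapped from '%s')",
                   dialect[[canonical]], canonical))
    data.table::setnames(raw, dialect[[canonical]], canonical)
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  raw <- as.data.frame(raw)
  if (nrow(raw)) {
    sentinel <- function(x, token) {
      x <- as.character(x)
      x[is.na(x) | !nzchar(x) | tolower(x) == "unclassified"] <- token
      x
    }
    unc_gen <- is.na(raw$genus) | !nzchar(as.character(raw$genus)) |
      tolower(as.character(raw$genus)) == "unclassified"
    raw$genus <- sentinel(raw$genus, UNCLASSIFIED_TAXON)
    raw$phylum[unc_gen] <- UNCLASSIFIED_TAXON
    unc_fun <- is.na(raw$function_id) | !nzchar(as.character(raw$function_id)) |
      tolower(as.character(raw$function_id)) == "unclassified"
    raw$function_id <- sentinel(raw$function_id, UNCLASSIFIED_FUNCTION)
    for (col in c("level1", "level2", "level3"))
      raw[[col]][unc_fun] <- UNCLASSIFIED_FUNCTION
    if (dropUnclassified)
      raw <- raw[raw$genus != UNCLASSIFIED_TAXON &
                 raw$function_id != UNCLASSIFIED_FUNCTION, , drop = FALSE]
  }
  linkedProfile(raw)
}

#' Write a LinkedProfile as canonical tab-separated text
#'
#' The written file round-trips: [readLinkedProfile()] on the output
#' reconstructs an identical record multiset.
#'
#' @param profile a [LinkedProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLinkedProfile <- function(profile, path) {
  stopifnot(is(profile, "LinkedProfile"))
  data.table::fwrite(profileRecords(profile), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Project a joint profile to a one-level abundance table
#'
#' Sums hits over all records mapping to each feature at the requested
#' hierarchy level. Total hits are conserved:
#' `sum(projectProfile(p, k, l)) == sum(profileRecords(p)$hits)` for every
#' valid (kind, level).
#'
#' @param profile a [LinkedProfile-class].
#' @param kind `"taxonomy"` or `"function"`.
#' @param level `"phylum"`/`"genus"` for taxonomy; `"level1"`, `"level2"`,
#'   `"level3"` or `"function"` for function.
#' @return an [AbundanceTable-class] of counts (samples x features, features
#'   sorted lexicographically; all profile samples present as rows).
#' @export
projectProfile <- function(profile, kind = c("taxonomy", "function"),
                           level = NULL) {
  stopifnot(is(profile, "LinkedProfile"))
  kind <- match.arg(kind)
  valid <- if (kind == "taxonomy") TAXONOMY_LEVELS else FUNCTION_LEVELS
  if (is.null(level)) level <- if (kind == "taxonomy") "genus" else "function"
  if (!level %in% valid)
    stop(sprintf("unknown level '%s' for kind '%s' (valid: %s)",
                 level, kind, paste(valid, collapse = ", ")))
  rec <- profileRecords(profile)
  feature <- if (level == "function") rec$function_id else rec[[level]]
  samples <- sampleIds(profile)
  features <- sort(unique(feature))
  mat <- matrix(0, nrow = length(samples), ncol = length(features),
                dimnames = list(samples, features))
  if (nrow(rec)) {
    agg <- data.table::data.table(sample = rec$sample, feature = feature,
                                  hits = rec$hits)
    agg <- agg[, list(hits = sum(hits)), by = c("sample", "feature")]
    mat[cbind(agg$sample, agg$feature)] <- agg$hits
  }
  new("AbundanceTable", mat, kind = kind, level = level, relative = FALSE)
}

#' Standardize an abundance table to relative abundance
#'
#' Divides each sample row by its own total; all-zero rows are left as zero
#' and reported with a warning. Idempotent on already-normalized rows.
#'
#' @param table an [AbundanceTable-class].
#' @return the table with rows summing to 1 (or all zero) and
#'   `isRelative() == TRUE`.
#' @export
toRelativeAbundance <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  mat <- table@.Data
  totals <- rowSums(mat)
  zero <- totals == 0
  if (any(zero))
    warning("all-zero sample row(s) left unnormalized: ",
            paste(rownames(mat)[zero], collapse = ", "))
  mat[!zero, ] <- mat[!zero, , drop = FALSE] / totals[!zero]
  new("AbundanceTable", mat, kind = table@kind, level = table@level,
      relative = TRUE)
}

#' Summarize a count table into species (S) and individuals (N)
#'
#' S counts features whose pooled, across-sample hit total exceeds zero;
#' N is the grand total of hits. Only meaningful on counts: a
#' relative-abundance table is rejected.
#'
#' @param table an [AbundanceTable-class] of counts.
#' @return a [CommunitySummary-class].
#' @export
communitySummary <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (isRelative(table))
    stop("communitySummary requires counts; got a relative-abundance table")
  pooled <- colSums(table@.Data)
  new("CommunitySummary", S = sum(pooled > 0), N = sum(pooled))
}

setMethod("show", "CommunitySummary", function(object) {
  cat(sprintf("CommunitySummary: S = %g species, N = %g individuals\n",
              object@S, object@N))
})

#' Write an abundance table as tab-separated text
#'
#' @param table an [AbundanceTable-class].
#' @param path output path.
#' @param comments optional character vector written as `#`-prefixed header
#'   lines (stage provenance).
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(table, path, comments = character()) {
  stopifnot(is(table, "AbundanceTable"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  df <- data.frame(sample = rownames(table),
                   format(table@.Data, digits = 12, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an abundance table written by [writeAbundanceTable()]
#'
#' @param path input path.
#' @param kind,level,relative metadata to attach (not stored in the file body
#'   beyond comments).
#' @return an [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, kind = "taxonomy", level = "genus",
                               relative = FALSE) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  new("AbundanceTable", mat, kind = kind, level = level, relative = relative)
}
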