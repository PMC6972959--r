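#' Read a kinship table into a SampleObservation
#'
#' Reads a tab-separated kinship file in one of two dialects, detected from
#' the header line:
#' \describe{
#'   \item{`offspring_id`, `mother_id`}{one row per sampled offspring;
#'     `H_obs` is computed as `sum(choose(m_j, 2))` over the multiplicities
#'     m_j of each mother ID. Duplicate offspring IDs are rejected.}
#'   \item{`id1`, `id2`, `is_mhs`}{one row per offspring pair with a 0/1
#'     MHS flag; `H_obs = sum(is_mhs)` and n is recovered from the number of
#'     distinct IDs. Full-sib pairs must already be flagged as MHS (they
#'     count as MHS by definition).}
#' }
#'
#' @param path path to the TSV file.
#' @return A [SampleObservation-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("offspring_id\tmother_id", "o1\tA", "o2\tA", "o3\tB"), tf)
#' readKinshipTable(tf)
#' @export
readKinshipTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("kinship table must contain a header and at least one data row: ",
         path)
  header <- tolower(trimws(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)

  if (identical(header, c("offspring_id", "mother_id"))) {
    bad <- which(lengths(body) != 2L)
    if (length(bad))
      stop("malformed row (expected 2 tab-separated fields) at line ",
           bad[1L] + 1L)
    off <- trimws(vapply(body, `[[`, "", 1L))
    mom <- trimws(vapply(body, `[[`, "", 2L))
    if (any(!nzchar(off)) || any(!nzchar(mom)))
      stop("empty ID at line ",
           which(!nzchar(off) | !nzchar(mom))[1L] + 1L)
    if (anyDuplicated(off))
      stop("duplicate offspring ID '", off[duplicated(off)][1L],
           "' at line ", which(duplicated(off))[1L] + 1L)
    return(SampleObservation(length(off), countMhsPairs(mom)))
  }

  if (identical(header, c("id1", "id2", "is_mhs"))) {
    bad <- which(lengths(body) != 3L)
    if (length(bad))
      stop("malformed row (expected 3 tab-separated fields) at line ",
           bad[1L] + 1L)
    id1 <- trimws(vapply(body, `[[`, "", 1L))
    id2 <- trimws(vapply(body, `[[`, "", 2L))
    flag <- trimws(vapply(body, `[[`, "", 3L))
    if (!all(flag %in% c("0", "1")))
      stop("is_mhs must be 0 or 1 at line ",
           which(!flag %in% c("0", "1"))[1L] + 1L)
    n <- length(unique(c(id1, id2)))
    npr <- nPairs(n)
    if (length(body) != npr)
      stop("expected ", npr, " pair rows for ", n,
           " distinct offspring, found ", length(body))
    return(SampleObservation(n, sum(flag == "1")))
  }

  stop("unknown kinship-table columns: ", paste(header, collapse = ", "),
       " (expected offspring_id/mother_id or id1/id2/is_mhs)")
}

#' Write experiment or estimate results to disk
#'
#' Writes a per-replicate CSV (`<prefix>_replicates.csv`) and a summary JSON
#' (`<prefix>_summary.json`) for an experiment object from [runExperiment()]
#' or [runTemporalExperiment()], or a single JSON for a
#' [NeEstimates-class]. Every summary embeds the configuration, the seed,
#' and a hash of the configuration, so outputs are traceable to their run.
#'
#' @param results an `hsExperiment`, `tmExperiment`, or
#'   [NeEstimates-class] object.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(results, prefix) {
  if (is(results, "NeEstimates")) {
    path <- paste0(prefix, "_estimates.json")
    jsonlite::write_json(as.data.frame(results), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    return(invisible(path))
  }
  if (!inherits(results, c("hsExperiment", "tmExperiment")))
    stop("unsupported results object of class ", class(results)[1L])
  csvPath <- paste0(prefix, "_replicates.csv")
  jsonPath <- paste0(prefix, "_summary.json")
  utils::write.csv(results$replicates, csvPath, row.names = FALSE)
  payload <- list(summary = results$summary, config = results$config,
                  seed = results$config$seed,
                  configHash = rlang::hash(results$config))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csvPath, jsonPath))
}
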