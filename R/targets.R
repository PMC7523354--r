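#' Load a miRNA target-prediction table
#'
#' Expects the columns `mirna_id`, `target_id`, `target_class` (lncRNA or
#' mRNA) and `programs` (comma-joined programme labels). Duplicate
#' (miRNA, target) rows are merged by programme-set union, so exports that
#' repeat an interaction once per programme load cleanly.
#'
#' @param path TSV file.
#' @return prediction data frame with an added `n_programs` column.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_class", "programs")
  if (!all(need %in% names(df)))
    stop("prediction table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$mirna_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    merged <- lapply(split(df, key), function(grp) {
      progs <- unique(unlist(strsplit(grp$programs, ",")))
      grp <- grp[1, , drop = FALSE]
      grp$programs <- paste(sort(progs), collapse = ",")
      grp
    })
    df <- do.call(rbind, merged)
    rownames(df) <- NULL
  }
  count_programs(df)
}

count_programs <- function(records) {
  records$n_programs <- vapply(
    strsplit(records$programs, ","),
    function(p) length(unique(p[nzchar(p)])), 0L)
  records
}

#' Programme-vote consensus filter
#'
#' Keeps records supported by at least `min_programs` prediction programmes.
#' By default the rule applies to mRNA targets only; lncRNA records pass
#' unfiltered. Extend via `apply_to = c("mRNA", "lncRNA")`.
#'
#' @param records prediction data frame (see [read_predictions()]).
#' @param min_programs minimum distinct programmes (default 4).
#' @param apply_to target classes the vote rule applies to.
#' @return filtered prediction data frame.
#' @export
vote_filter <- function(records, min_programs = 4, apply_to = "mRNA") {
  stopifnot(min_programs >= 1)
  if (is.null(records$n_programs)) records <- count_programs(records)
  keep <- !(records$target_class %in% apply_to) |
    records$n_programs >= min_programs
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect predicted targets with the differentially expressed lists
#'
#' Retains prediction records whose target is differentially expressed:
#' mRNA targets against `de_mrnas`, lncRNA targets against `de_lncrnas`.
#'
#' @param records vote-filtered prediction data frame.
#' @param de_mrnas,de_lncrnas character vectors of DE feature ids.
#' @return list with `records` (retained rows), `dems` and `dels` (the
#'   intersected mRNA / lncRNA id sets). An empty intersection warns.
#' @export
merge_with_de <- function(records, de_mrnas, de_lncrnas) {
  keep <- (records$target_class == "mRNA" & records$target_id %in% de_mrnas) |
    (records$target_class == "lncRNA" & records$target_id %in% de_lncrnas)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no predicted target is differentially expressed; empty result")
  list(records = out,
       dems = sort(unique(out$target_id[out$target_class == "mRNA"])),
       dels = sort(unique(out$target_id[out$target_class == "lncRNA"])))
}

#' Drop candidate miRNAs with no surviving target
#'
#' After vote filtering and the DE merge, candidate miRNAs without a single
#' retained prediction record are removed from the analysis.
#'
#' @param records retained prediction records.
#' @param candidate_mirnas character vector of candidate miRNA ids.
#' @return list with `kept` and `removed` miRNA id vectors (both sorted).
#' @export
prune_mirnas <- function(records, candidate_mirnas) {
  covered <- unique(records$mirna_id)
  kept <- sort(intersect(candidate_mirnas, covered))
  list(kept = kept, removed = sort(setdiff(candidate_mirnas, covered)))
}
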