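# BUSCO-based extension of curated reference gene sets. BUSCO itself is
# never run here; its per-ortholog assessment table is consumed.

BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Read a BUSCO `full_table.tsv`
#'
#' Tab-separated with `#` comment lines; columns are BUSCO id, status,
#' sequence id, score and length, with any trailing columns tolerated.
#' `Missing` rows carry no sequence. Statuses outside
#' Complete/Duplicated/Fragmented/Missing raise an error naming the line.
#'
#' @param file Path to a BUSCO full table, or a character vector of lines.
#' @return A tibble: `busco_id`, `status` (factor), `sequence_id`,
#'   `score`, `length`.
#' @export
read_busco_table <- function(file) {
  if (length(file) == 1 && !grepl("\t|\n", file) && !file.exists(file)) {
    stop("read_busco_table: file not found: '", file, "'", call. = FALSE)
  }
  lines <- if (length(file) == 1 && !grepl("\t|\n", file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  recs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 2) {
      stop("BUSCO table line ", lineno[i],
           ": expected at least 2 tab-separated columns", call. = FALSE)
    }
    status <- trimws(f[2])
    if (!status %in% BUSCO_STATUSES) {
      stop("BUSCO table line ", lineno[i], ": unknown status '", status,
           "' (expected ", paste(BUSCO_STATUSES, collapse = "/"), ")",
           call. = FALSE)
    }
    if (status != "Missing" && length(f) < 3) {
      stop("BUSCO table line ", lineno[i],
           ": non-Missing row lacks a sequence column", call. = FALSE)
    }
    recs[[i]] <- tibble::tibble(
      busco_id = trimws(f[1]),
      status = status,
      sequence_id = if (status == "Missing" || length(f) < 3 ||
                          !nzchar(trimws(f[3]))) {
        NA_character_
      } else {
        trimws(f[3])
      },
      score = if (length(f) >= 4) suppressWarnings(as.numeric(f[4])) else
        NA_real_,
      length = if (length(f) >= 5) suppressWarnings(as.integer(f[5])) else
        NA_integer_
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(busco_id = character(), status = character(),
                          sequence_id = character(), score = numeric(),
                          length = integer())
  }
  out$status <- factor(out$status, levels = BUSCO_STATUSES)
  out
}

#' Partition BUSCO records by curation status of their gene
#'
#' Splits records into curated (sequence id in `curated_ids`) and
#' uncurated; `Missing` records have no gene to assign and belong to
#' neither group.
#'
#' @param records Tibble from [read_busco_table()].
#' @param curated_ids Character vector of curated gene identifiers
#'   (e.g. Swiss-Prot-backed).
#' @return The non-Missing records with an added `group` column
#'   (`"curated"` / `"uncurated"`).
#' @export
partition_by_curation <- function(records, curated_ids) {
  out <- records[records$status != "Missing" & !is.na(records$sequence_id), ,
                 drop = FALSE]
  out$group <- ifelse(out$sequence_id %in% curated_ids,
                      "curated", "uncurated")
  tibble::as_tibble(out)
}

#' z-test of fragmented-to-complete proportions between two record groups
#'
#' For each group the proportion tested is
#' `Fragmented / (Fragmented + complete-class)` where the complete class
#' is Complete plus, by default, Duplicated. Delegates to
#' [two_proportion_ztest()]. Used to check that curated and uncurated
#' genes fragment at indistinguishable rates before pooling them into one
#' gold standard.
#'
#' @param group_1,group_2 Tibbles of BUSCO records (e.g. the two halves of
#'   [partition_by_curation()]).
#' @param complete_class Statuses counted as complete
#'   (default Complete and Duplicated).
#' @return A `prop_ztest` object with an added `ratios` element giving
#'   each group's fragmented proportion and trial count.
#' @export
fragmented_complete_ztest <- function(group_1, group_2,
                                      complete_class = c("Complete",
                                                         "Duplicated")) {
  count_group <- function(g, name) {
    frag <- sum(g$status == "Fragmented")
    comp <- sum(as.character(g$status) %in% complete_class)
    if (frag + comp == 0) {
      stop("fragmented_complete_ztest: group ", name,
           " has no Fragmented or complete-class records", call. = FALSE)
    }
    list(frag = frag, trials = frag + comp)
  }
  c1 <- count_group(group_1, "1")
  c2 <- count_group(group_2, "2")
  test <- two_proportion_ztest(c1$frag, c1$trials, c2$frag, c2$trials)
  test$ratios <- tibble::tibble(
    group = c("group_1", "group_2"),
    fragmented = c(c1$frag, c2$frag),
    trials = c(c1$trials, c2$trials),
    proportion = c(c1$frag / c1$trials, c2$frag / c2$trials)
  )
  test
}

#' Build an extended gold-standard reference gene set
#'
#' The gold standard is the union of curated gene ids and the ids of
#' uncurated genes whose protein BUSCO reports in a complete-class status.
#' Curated genes are kept regardless of their own BUSCO status (curation
#' is the higher evidence tier); one complete-class record suffices when
#' several BUSCO records point at the same gene.
#'
#' @param records Tibble from [read_busco_table()].
#' @param curated_ids Character vector of curated gene ids (may be empty).
#' @param complete_class Statuses accepted as complete (default Complete
#'   and Duplicated; set to `"Complete"` for the strict variant).
#' @param organism_label Free-text label carried into the summary.
#' @return A tibble of class `gold_standard`: `gene_id`, `provenance`
#'   (`curated`, `busco_complete`, or `both`). The attribute `"summary"`
#'   holds counts and the percent increase
#'   `100 * added / curated` (`NA` when no curated genes exist).
#' @export
build_gold_standard <- function(records, curated_ids,
                                complete_class = c("Complete", "Duplicated"),
                                organism_label = "organism") {
  curated_ids <- unique(curated_ids)
  complete_seqs <- unique(records$sequence_id[
    as.character(records$status) %in% complete_class &
      !is.na(records$sequence_id)])
  added <- setdiff(complete_seqs, curated_ids)
  members <- tibble::tibble(
    gene_id = c(curated_ids, added),
    provenance = c(
      ifelse(curated_ids %in% complete_seqs, "both", "curated"),
      rep("busco_complete", length(added))
    )
  )
  members <- members[order(members$gene_id), , drop = FALSE]
  summary <- list(
    organism = organism_label,
    n_curated = length(curated_ids),
    n_busco_added = length(added),
    n_total = nrow(members),
    percent_increase = if (length(curated_ids) > 0) {
      100 * length(added) / length(curated_ids)
    } else {
      NA_real_
    }
  )
  structure(members, class = c("gold_standard", class(members)),
            summary = summary)
}

#' @export
print.gold_standard <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("<gold_standard> %s: %d member(s) = %d curated + %d ",
                     "BUSCO-complete (%s%% increase)\n"),
              s$organism, s$n_total, s$n_curated, s$n_busco_added,
              if (is.na(s$percent_increase)) "NA" else
                formatC(s$percent_increase, format = "fg", digits = 4)))
  NextMethod()
}

#' @rdname build_gold_standard
#' @param x A `gold_standard` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.gold_standard <- function(x, ...) {
  tibble::as_tibble(attr(x, "summary"))
}
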