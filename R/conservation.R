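## Alignment-column conservation statistic: anchor filtering, six-group
## BLOSUM62 similarity classes, conserved / similar / dissimilar /
## PCMH-unlike categorisation, and residue-group summaries.

#' BLOSUM62-derived amino-acid similarity groups
#'
#' The six residue sets used to score column preservation: aromatic
#' (W, Y, F), aliphatic (M, I, L, V), basic (H, R, K), acidic/amide
#' (N, D, Q, E), small (S, T, P, A, G) and cysteine alone. The sets
#' partition the 20 standard amino acids; non-standard letters (X, B, Z,
#' U) and gaps belong to no group.
#'
#' @return named list of character vectors, in the alphabetical name
#'   order used for deterministic tie-breaking.
#' @export
similarity_groups <- function() {
  list(acidic_amide = c("N", "D", "Q", "E"),
       aliphatic    = c("M", "I", "L", "V"),
       aromatic     = c("W", "Y", "F"),
       basic        = c("H", "R", "K"),
       cys          = "C",
       small        = c("S", "T", "P", "A", "G"))
}

#' Labelled multiple sequence alignment
#'
#' Container for an aligned FASTA with optional subfamily labels (VAO /
#' EUGO / PCMH) per record and one designated query record whose ungapped
#' positions define the coordinate system.
#'
#' @param seqs character matrix, records x columns, upper case, gaps `-`.
#' @param ids record identifiers.
#' @param labels optional character vector of subfamily labels per record.
#' @param query id of the query record (default the first record).
#' @return object of class `"msa"`.
#' @export
msa <- function(seqs, ids, labels = NULL, query = ids[1]) {
  stopifnot(is.matrix(seqs), nrow(seqs) == length(ids))
  if (!query %in% ids) stopf("query '%s' not among record ids", query)
  if (!is.null(labels) && length(labels) != length(ids))
    stopf("labels must match the number of records")
  rownames(seqs) <- ids
  structure(list(seqs = seqs, ids = ids, labels = labels, query = query),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Alignment: %d records x %d columns (query: %s)\n",
              nrow(x$seqs), ncol(x$seqs), x$query))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Loads an alignment via [Biostrings::readAAStringSet()]; records keep
#' file order, characters are upper-cased and `.` gaps normalised to `-`.
#' Ragged alignments are an error naming the offending record.
#'
#' @param file FASTA path.
#' @param labels optional subfamily labels: a named character vector
#'   (names = record ids) or the path to a two-column TSV (`id`,
#'   `label`).
#' @param query query record id (default the first record).
#' @return an `"msa"` object.
#' @export
read_msa <- function(file, labels = NULL, query = NULL) {
  ss <- Biostrings::readAAStringSet(file)
  ids <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1) {
    bad <- ids[which(w != w[1])[1]]
    stopf("ragged alignment in %s: record '%s' has length %d, expected %d",
          file, bad, w[ids == bad][1], w[1])
  }
  chars <- toupper(as.character(ss))
  chars <- gsub(".", "-", chars, fixed = TRUE)
  seqs <- do.call(rbind, strsplit(chars, ""))
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    tb <- read.delim(labels, stringsAsFactors = FALSE)
    labels <- setNames(tb[[2]], tb[[1]])
  }
  if (!is.null(labels)) labels <- unname(labels[ids])
  msa(seqs, ids, labels, query %||% ids[1])
}

#' @rdname read_msa
#' @param x an `"msa"` object.
#' @export
write_msa <- function(x, file) {
  ss <- Biostrings::AAStringSet(apply(x$seqs, 1, paste, collapse = ""))
  names(ss) <- x$ids
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Map alignment columns to query positions
#'
#' Columns where the query is gapped are excluded; remaining columns are
#' numbered 1..(ungapped query length).
#'
#' @param x an `"msa"`.
#' @return list with `col_for_pos` (alignment column per query position)
#'   and `n_positions`.
#' @export
map_columns_to_query <- function(x) {
  q <- x$seqs[x$query, ]
  cols <- which(q != "-")
  list(col_for_pos = cols, n_positions = length(cols))
}

#' Filter records by a covalent-anchor residue
#'
#' Retains only records carrying one of `required` residues in the column
#' corresponding to a query position — the covalent FAD anchor (His422 in
#' VAO numbering; His390 for EUGO-like, Tyr384 for PCMH-like records).
#' The query itself is always retained.
#'
#' @param x an `"msa"`.
#' @param query_position anchor position in query numbering.
#' @param required residues accepted at the anchor (e.g. `"H"`).
#' @return the filtered `"msa"`.
#' @export
filter_covalent_anchor <- function(x, query_position, required = "H") {
  map <- map_columns_to_query(x)
  if (query_position < 1 || query_position > map$n_positions)
    stopf("query position %d outside 1..%d", query_position, map$n_positions)
  col <- map$col_for_pos[query_position]
  keep <- x$seqs[, col] %in% required | x$ids == x$query
  msa(x$seqs[keep, , drop = FALSE], x$ids[keep],
      if (!is.null(x$labels)) x$labels[keep], x$query)
}

#' Dominant similarity group of an alignment column
#'
#' The fraction of the column falling in its most populated similarity
#' group. Under the default gap policy (`"count"`) gaps count in the
#' denominator and belong to no group, so a gap-heavy column cannot score
#' as similar; `"exclude"` drops gaps from the denominator. Group ties go
#' to the alphabetically first group name and are flagged.
#'
#' @param column character vector of residues (one alignment column).
#' @param groups similarity groups, see [similarity_groups()].
#' @param gap_policy `"count"` (default) or `"exclude"`.
#' @return list: `group` (name or `NA` for an all-gap column),
#'   `fraction`, `tie` (logical).
#' @export
column_similarity <- function(column, groups = similarity_groups(),
                              gap_policy = c("count", "exclude")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(column) >= 1)
  counts <- vapply(groups, function(g) sum(column %in% g), integer(1))
  denom <- if (gap_policy == "count") length(column)
           else sum(column %in% unlist(groups))
  if (denom == 0 || all(counts == 0))
    return(list(group = NA_character_, fraction = 0, tie = FALSE))
  m <- max(counts)
  at <- which(counts == m)
  list(group = names(groups)[at[1]], fraction = m / denom,
       tie = length(at) > 1)
}

#' Categorise an alignment position
#'
#' Single-subfamily mode: conserved when the dominant-group fraction is
#' strictly above `conserved_cutoff` (0.90), similar when at least
#' `similar_cutoff` (0.50), dissimilar otherwise. Merged mode
#' (per-subfamily rule): the position is similar when all three
#' subfamilies share one identical dominant group, each with fraction at
#' least 0.50; conserved when additionally every fraction exceeds 0.90;
#' dissimilar otherwise. A dissimilar position is PCMH-unlike when the
#' VAO and EUGO subfamilies share an identical dominant group (each at
#' least 0.50) but the PCMH subfamily's dominant group differs or falls
#' below 0.50.
#'
#' @param stats single mode: one result of [column_similarity()]; merged
#'   mode: a named list of such results for `VAO`, `EUGO`, `PCMH`.
#' @param similar_cutoff,conserved_cutoff category cutoffs (0.50
#'   inclusive / 0.90 strict).
#' @param mode `"single"` or `"merged"`.
#' @return list: `category` in conserved/similar/dissimilar and
#'   `pcmh_unlike` (always `FALSE` in single mode).
#' @export
categorise_position <- function(stats, similar_cutoff = 0.50,
                                conserved_cutoff = 0.90,
                                mode = c("single", "merged")) {
  mode <- match.arg(mode)
  stopifnot(similar_cutoff > 0, similar_cutoff < conserved_cutoff,
            conserved_cutoff <= 1)
  if (mode == "single") {
    f <- stats$fraction
    cat <- if (f > conserved_cutoff) "conserved"
      else if (f >= similar_cutoff) "similar" else "dissimilar"
    return(list(category = cat, pcmh_unlike = FALSE))
  }
  need <- c("VAO", "EUGO", "PCMH")
  if (!all(need %in% names(stats)))
    stopf("merged mode needs stats for subfamilies: %s",
          paste(setdiff(need, names(stats)), collapse = ", "))
  g <- vapply(stats[need], function(s) s$group %||% NA_character_,
              character(1))
  f <- vapply(stats[need], `[[`, numeric(1), "fraction")
  shared_all <- !anyNA(g) && length(unique(g)) == 1 &&
    all(f >= similar_cutoff)
  if (shared_all && all(f > conserved_cutoff))
    return(list(category = "conserved", pcmh_unlike = FALSE))
  if (shared_all)
    return(list(category = "similar", pcmh_unlike = FALSE))
  ve_share <- !anyNA(g[c("VAO", "EUGO")]) && g["VAO"] == g["EUGO"] &&
    all(f[c("VAO", "EUGO")] >= similar_cutoff)
  pcmh_off <- is.na(g["PCMH"]) || g["PCMH"] != g["VAO"] ||
    f["PCMH"] < similar_cutoff
  list(category = "dissimilar",
       pcmh_unlike = unname(ve_share && pcmh_off))
}

#' Per-position conservation profile of a labelled alignment
#'
#' Runs the column-similarity and categorisation machinery over all query
#' positions. With subfamily labels covering VAO/EUGO/PCMH the merged
#' rules apply (per-subfamily agreement by default; `merged_rule =
#' "pooled"` scores the pooled column instead, with PCMH-unlikeness still
#' judged per subfamily); without labels the single-alignment rules
#' apply.
#'
#' @param x an `"msa"`.
#' @param groups similarity groups.
#' @param similar_cutoff,conserved_cutoff category cutoffs.
#' @param gap_policy `"count"` or `"exclude"`, see [column_similarity()].
#' @param merged_rule `"per_subfamily"` (default) or `"pooled"`.
#' @return data.frame of class `"conservation_profile"`: one row per
#'   query position with the alignment column, per-subfamily dominant
#'   group and fraction (merged mode), category and `pcmh_unlike` flag.
#' @export
conservation_profile <- function(x, groups = similarity_groups(),
                                 similar_cutoff = 0.50,
                                 conserved_cutoff = 0.90,
                                 gap_policy = c("count", "exclude"),
                                 merged_rule = c("per_subfamily", "pooled")) {
  gap_policy <- match.arg(gap_policy)
  merged_rule <- match.arg(merged_rule)
  map <- map_columns_to_query(x)
  merged <- !is.null(x$labels)
  if (merged) {
    need <- c("VAO", "EUGO", "PCMH")
    if (!all(need %in% x$labels))
      stopf("merged mode needs records labelled %s; missing: %s",
            paste(need, collapse = "/"),
            paste(setdiff(need, x$labels), collapse = ", "))
  }
  rows <- lapply(seq_len(map$n_positions), function(p) {
    col <- x$seqs[, map$col_for_pos[p]]
    if (!merged) {
      cs <- column_similarity(col, groups, gap_policy)
      ct <- categorise_position(cs, similar_cutoff, conserved_cutoff,
                                "single")
      return(data.frame(position = p, column = map$col_for_pos[p],
                        group = cs$group, fraction = cs$fraction,
                        tie = cs$tie, category = ct$category,
                        pcmh_unlike = FALSE))
    }
    per <- lapply(c(VAO = "VAO", EUGO = "EUGO", PCMH = "PCMH"), function(lb)
      column_similarity(col[x$labels == lb], groups, gap_policy))
    if (merged_rule == "per_subfamily") {
      ct <- categorise_position(per, similar_cutoff, conserved_cutoff,
                                "merged")
    } else {
      pooled <- column_similarity(col, groups, gap_policy)
      base <- categorise_position(pooled, similar_cutoff, conserved_cutoff,
                                  "single")
      pu <- FALSE
      if (base$category == "dissimilar") {
        sub <- categorise_position(per, similar_cutoff, conserved_cutoff,
                                   "merged")
        pu <- sub$pcmh_unlike
      }
      ct <- list(category = base$category, pcmh_unlike = pu)
    }
    data.frame(position = p, column = map$col_for_pos[p],
               vao_group = per$VAO$group, vao_fraction = per$VAO$fraction,
               eugo_group = per$EUGO$group, eugo_fraction = per$EUGO$fraction,
               pcmh_group = per$PCMH$group, pcmh_fraction = per$PCMH$fraction,
               category = ct$category, pcmh_unlike = ct$pcmh_unlike)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- if (merged) "merged" else "single"
  attr(out, "config") <- list(similar_cutoff = similar_cutoff,
                              conserved_cutoff = conserved_cutoff,
                              gap_policy = gap_policy,
                              merged_rule = merged_rule)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' @export
print.conservation_profile <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Conservation profile: %d positions (%s mode, gap policy %s",
              nrow(x), attr(x, "mode"), cfg$gap_policy))
  if (attr(x, "mode") == "merged")
    cat(sprintf(", %s rule", cfg$merged_rule))
  cat(")\n")
  tb <- table(factor(x$category,
                     levels = c("conserved", "similar", "dissimilar")))
  for (k in names(tb))
    cat(sprintf("  %-10s %4d (%.1f%%)\n", k, tb[k], 100 * tb[k] / nrow(x)))
  if (any(x$pcmh_unlike))
    cat(sprintf("  PCMH-unlike %3d (%.1f%%)\n", sum(x$pcmh_unlike),
                100 * mean(x$pcmh_unlike)))
  invisible(x)
}

#' @export
summary.conservation_profile <- function(object, ...) {
  n <- nrow(object)
  data.frame(
    n_positions = n,
    pct_conserved = 100 * mean(object$category == "conserved"),
    pct_similar = 100 * mean(object$category == "similar"),
    pct_dissimilar = 100 * mean(object$category == "dissimilar"),
    pct_pcmh_unlike = 100 * mean(object$pcmh_unlike))
}

#' Category percentages per residue group
#'
#' For each named residue group (positions in query numbering) reports
#' the percentage of conserved / similar / dissimilar / PCMH-unlike
#' positions, with the group size as denominator.
#'
#' @param profile a `"conservation_profile"`.
#' @param residue_groups named list of integer position vectors.
#' @return data.frame: group, n, pct_conserved, pct_similar,
#'   pct_dissimilar, pct_pcmh_unlike.
#' @export
group_summary <- function(profile, residue_groups) {
  stopifnot(length(residue_groups) >= 1)
  n_pos <- nrow(profile)
  rows <- lapply(names(residue_groups), function(g) {
    pos <- residue_groups[[g]]
    bad <- pos[pos < 1 | pos > n_pos]
    if (length(bad))
      stopf("group '%s' references positions outside 1..%d: %s",
            g, n_pos, paste(head(bad, 5), collapse = ", "))
    if (!length(pos)) stopf("group '%s' is empty", g)
    sub <- profile[profile$position %in% pos, ]
    data.frame(group = g, n = nrow(sub),
               pct_conserved = 100 * mean(sub$category == "conserved"),
               pct_similar = 100 * mean(sub$category == "similar"),
               pct_dissimilar = 100 * mean(sub$category == "dissimilar"),
               pct_pcmh_unlike = 100 * mean(sub$pcmh_unlike))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default residue groups for conservation summaries
#'
#' The standard grouping used in path-conservation summaries: the entire
#' protein, the cap domain (residues 270-500), the four migration-path
#' sets ([vao_path_residues()]) and a fixed arbitrary selection of 58
#' positions standing in for the study's random control group (whose
#' exact membership was never published). Surface and interface groups
#' are structure-derived and supplied by the caller.
#'
#' @param n_positions protein length (default 560).
#' @return named list of integer vectors.
#' @export
default_residue_groups <- function(n_positions = 560) {
  paths <- vao_path_residues()
  list(entire_protein = seq_len(n_positions),
       cap_domain = 270:min(500, n_positions),
       random = unique(round(seq(5, n_positions - 4, length.out = 58))),
       cap_path = paths$cap, fad_path = paths$fad,
       interface_path = paths$subunit_interface, re_path = paths$re)
}

#' Write a conservation profile or group summary as TSV
#' @param x data.frame to write.
#' @param file output path.
#' @export
write_conservation_tsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
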