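# Table I/O and control-variant preprocessing.
#
# All tables are tab-separated with a header row; missing values are ".".
# Coordinates are 1-based inclusive; allele frequencies prefer the exome
# value over the genome value when both are present.

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = c(".", "NA", ""),
                    stringsAsFactors = FALSE, ...)
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score-set TSV
#'
#' Expected columns: `unit_id`, `score`, `label` with label in
#' \{P, B, U\}.
#'
#' @param path TSV path.
#' @param unit Optional unit id filter.
#' @return A [score_set()] (first unit if several and `unit` not given).
#' @export
read_score_set <- function(path, unit = NULL) {
  df <- read_tsv(path)
  stopifnot(all(c("unit_id", "score", "label") %in% names(df)))
  if (is.null(unit)) unit <- df$unit_id[1]
  df <- df[df$unit_id == unit, , drop = FALSE]
  score_set(pathogenic = df$score[df$label == "P"],
            benign = df$score[df$label == "B"],
            unlabeled = if (any(df$label == "U")) df$score[df$label == "U"] else NULL,
            unit_id = unit)
}

#' Write a score set to TSV
#' @param data A [score_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_set <- function(data, path) {
  stopifnot(inherits(data, "score_set"))
  df <- data.frame(
    unit_id = data$unit_id,
    score = c(data$pathogenic, data$benign, data$unlabeled %||% numeric(0)),
    label = c(rep("P", length(data$pathogenic)), rep("B", length(data$benign)),
              rep("U", length(data$unlabeled %||% numeric(0)))))
  write_tsv(df, path)
}

#' Read a variant table (ClinVar-style tab-delimited subset)
#'
#' @param path TSV path.
#' @param column_map Named character vector mapping canonical field names
#'   (`gene`, `chrom`, `pos`, `ref`, `alt`, `protein_pos`, `label`,
#'   `review_stars`, `af_exome`, `af_genome`, `splice_score`, `score`) to
#'   file column names; defaults to identity.
#' @return data.frame with canonical columns plus `allele_freq` (exome AF
#'   preferred over genome AF).
#' @export
read_variants <- function(path, column_map = NULL) {
  df <- read_tsv(path)
  canon <- c("gene", "chrom", "pos", "ref", "alt", "protein_pos", "label",
             "review_stars", "af_exome", "af_genome", "splice_score", "score")
  if (!is.null(column_map)) {
    for (k in names(column_map))
      if (column_map[[k]] %in% names(df)) names(df)[names(df) == column_map[[k]]] <- k
  }
  for (k in setdiff(canon, names(df))) df[[k]] <- NA
  df$allele_freq <- ifelse(!is.na(df$af_exome), df$af_exome, df$af_genome)
  df
}

#' Filter control variants per the preprocessing rules
#'
#' Keeps missense SNVs (single-base ref/alt when provided) with review
#' status of at least one star, allele frequency below 0.01 (missing AF
#' retained), splice-impact score below 0.2 (missing retained), and not on
#' the training exclusion list. Malformed rows (non-numeric score outside
#' [0, 1]) are logged and skipped.
#'
#' @param records data.frame from [read_variants()].
#' @param training_exclusion_list Character vector of variant keys
#'   (`chrom:pos:ref:alt`) to drop.
#' @param af_max AF cutoff (default 0.01, strict `<`).
#' @param splice_max Splice-score cutoff (default 0.2, strict `<`).
#' @param require_plp_gene Keep only genes with at least one P/LP record
#'   (default TRUE).
#' @return Filtered data.frame; attribute `n_skipped` counts malformed rows.
#' @export
filter_controls <- function(records, training_exclusion_list = character(0),
                            af_max = 0.01, splice_max = 0.2,
                            require_plp_gene = TRUE) {
  n0 <- nrow(records)
  malformed <- !is.na(records$score) &
    (!is.finite(suppressWarnings(as.numeric(records$score))) |
     records$score < 0 | records$score > 1)
  if (any(malformed))
    message(sum(malformed), " malformed rows skipped")
  r <- records[!malformed, , drop = FALSE]
  snv <- is.na(r$ref) | (nchar(as.character(r$ref)) == 1 &
                         nchar(as.character(r$alt)) == 1)
  stars <- !is.na(r$review_stars) & r$review_stars >= 1
  af <- is.na(r$allele_freq) | r$allele_freq < af_max
  spl <- is.na(r$splice_score) | r$splice_score < splice_max
  key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
  excl <- key %in% training_exclusion_list
  r <- r[snv & stars & af & spl & !excl, , drop = FALSE]
  if (require_plp_gene) {
    plp_genes <- unique(r$gene[r$label %in% c("P", "P/LP", "LP")])
    r <- r[r$gene %in% plp_genes, , drop = FALSE]
  }
  attr(r, "n_skipped") <- sum(malformed)
  r
}

#' Read a domain interval table
#'
#' Expected columns: `gene`, `start`, `end`, `domain_id`.
#' @param path TSV path.
#' @return data.frame of intervals.
#' @export
read_domains <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "start", "end", "domain_id") %in% names(df)))
  df
}

#' Write cluster assignments to TSV
#' @param clusters Named cluster id per domain key (`gene:domain_id`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  keys <- strsplit(names(clusters), ":", fixed = TRUE)
  df <- data.frame(gene = vapply(keys, `[`, character(1), 1),
                   domain = vapply(keys, function(k) paste(k[-1], collapse = ":"),
                                   character(1)),
                   cluster = unname(unlist(clusters)))
  write_tsv(df, path)
}
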