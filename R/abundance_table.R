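# Samples x taxa count container with rank-resolved lineage and sample
# metadata, plus readers/writers for QIIME-style TSV and BIOM JSON.

#' Taxonomic ranks recognised in lineage strings
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Construct an abundance table
#'
#' The central container of the profiling stage: a samples x taxa matrix
#' of non-negative integer counts, per-sample metadata (condition, day,
#' replicate) and per-taxon lineage resolved into up to 7 ranks.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames; entries must be non-negative integers.
#' @param samples `data.frame` of sample metadata, one row per sample in
#'   the order of `rownames(counts)`.  Optional columns `condition`,
#'   `day`, `replicate` are used downstream.
#' @param taxonomy `data.frame` of lineage, one row per taxon, columns a
#'   subset of [TAXONOMY_RANKS]; or a character vector of QIIME-style
#'   lineage strings (`"k__Bacteria; p__Firmicutes; ..."`).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, samples = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("sample_%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("taxon_%03d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    abort("sample ids must be unique", "digestor_contract_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("counts must be non-negative integers", "digestor_contract_error")
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(counts))
  } else {
    samples <- as.data.frame(samples)
    if (!"sample_id" %in% names(samples)) {
      samples$sample_id <- rownames(counts)
    }
    stopifnot(nrow(samples) == nrow(counts))
  }
  rownames(samples) <- samples$sample_id
  if (is.character(taxonomy)) taxonomy <- parse_lineage(taxonomy)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(row.names = colnames(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    stopifnot(nrow(taxonomy) == ncol(counts))
    bad <- setdiff(names(taxonomy), TAXONOMY_RANKS)
    if (length(bad)) {
      abort(paste0("unknown lineage ranks: ", paste(bad, collapse = ", ")),
            "digestor_domain_error")
    }
    rownames(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, samples = samples, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (%s ranks)\n",
              nrow(x$counts), ncol(x$counts),
              if (ncol(x$taxonomy)) paste(names(x$taxonomy), collapse = ">")
              else "no"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Parse QIIME-style lineage strings
#'
#' Accepts `"k__Bacteria; p__Firmicutes; g__Trichococcus"` style strings
#' (prefixes `k`/`d`, `p`, `c`, `o`, `f`, `g`, `s`; separators `;` with
#' optional spaces).  Empty fields become `NA`.
#'
#' @param lineages character vector.
#' @return `data.frame` with columns from [TAXONOMY_RANKS].
#' @export
parse_lineage <- function(lineages) {
  prefix_map <- c(k = "domain", d = "domain", p = "phylum", c = "class",
                  o = "order", f = "family", g = "genus", s = "species")
  out <- matrix(NA_character_, nrow = length(lineages),
                ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    depth <- 0L
    for (p in parts) {
      if (grepl("^[kdpcofgs]__", p)) {
        rank <- prefix_map[[substr(p, 1, 1)]]
        val <- sub("^[kdpcofgs]__", "", p)
      } else {
        depth <- depth + 1L
        if (depth > length(TAXONOMY_RANKS)) next
        rank <- TAXONOMY_RANKS[depth]
        val <- p
      }
      if (nzchar(val)) out[i, rank] <- val
    }
  }
  keep <- colSums(!is.na(out)) > 0
  as.data.frame(out[, keep, drop = FALSE])
}

format_lineage <- function(taxonomy) {
  prefixes <- c(domain = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__",
                species = "s__")
  ranks <- intersect(TAXONOMY_RANKS, names(taxonomy))
  if (!length(ranks)) return(rep("", nrow(taxonomy)))
  apply(taxonomy[, ranks, drop = FALSE], 1L, function(row) {
    paste0(prefixes[ranks],
           ifelse(is.na(row), "", row), collapse = "; ")
  })
}

#' Read an OTU table from TSV
#'
#' QIIME-classic layout: taxa in rows, samples in columns, an optional
#' lineage column, `#`-prefixed comment lines, and a header line that
#' may itself start with `#OTU ID`.
#'
#' @param path file path.
#' @param lineage_col name of the lineage column (case-insensitive
#'   match on `"taxonomy"`/`"lineage"` by default).
#' @param samples optional sample metadata `data.frame` (rows matched to
#'   sample ids by the `sample_id` column).
#' @return An [abundance_table()].
#' @export
read_otu_table <- function(path, lineage_col = NULL, samples = NULL) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU")
  lines <- lines[!is_comment]
  if (!length(lines)) abort("empty OTU table", "digestor_parse_error")
  df <- utils::read.delim(text = lines, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  taxon_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (is.null(lineage_col)) {
    hit <- grep("^(taxonomy|lineage)$", names(df), ignore.case = TRUE)
    lineage_col <- if (length(hit)) names(df)[hit[1]] else NA
  }
  lineage <- NULL
  if (!is.na(lineage_col) && lineage_col %in% names(df)) {
    lineage <- as.character(df[[lineage_col]])
    df <- df[, setdiff(names(df), lineage_col), drop = FALSE]
  }
  counts <- t(as.matrix(df))
  colnames(counts) <- taxon_ids
  taxonomy <- if (!is.null(lineage)) parse_lineage(lineage)
  if (!is.null(samples)) {
    samples <- samples[match(rownames(counts), samples$sample_id), ,
                       drop = FALSE]
  }
  abundance_table(counts, samples = samples, taxonomy = taxonomy)
}

#' Write an abundance table as QIIME-classic TSV
#'
#' @param t an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  out <- as.data.frame(t(t$counts), check.names = FALSE)
  out <- cbind(`#OTU ID` = colnames(t$counts), out)
  if (ncol(t$taxonomy)) out$taxonomy <- format_lineage(t$taxonomy)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIOM-format (JSON) OTU table
#'
#' Requires the `biomformat` package.
#'
#' @param path path to a JSON BIOM file.
#' @return An [abundance_table()].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the 'biomformat' package is required to read BIOM files",
          "digestor_dependency_error")
  }
  b <- biomformat::read_biom(path)
  counts <- t(as.matrix(biomformat::biom_data(b)))  # -> samples x taxa
  md <- biomformat::observation_metadata(b)
  taxonomy <- NULL
  if (!is.null(md) && length(md)) {
    lin <- if (is.data.frame(md)) {
      apply(md, 1L, paste, collapse = "; ")
    } else {
      vapply(md, function(x) paste(unlist(x), collapse = "; "),
             character(1))
    }
    taxonomy <- parse_lineage(unname(lin))
  }
  abundance_table(counts, taxonomy = taxonomy)
}

#' Read sample metadata TSV
#'
#' Expects at least a `sample_id` column; `condition`, `day` and
#' `replicate` are used by downstream stages.
#'
#' @param path file path.
#' @return A `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  if (!"sample_id" %in% names(df)) {
    abort("sample metadata must contain a 'sample_id' column",
          "digestor_contract_error")
  }
  df
}
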