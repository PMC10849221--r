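#' Read a (possibly wrapped) multi-record FASTA file
#'
#' Sequences are case-folded to upper case, internal whitespace is stripped
#' and RNA `U` is mapped to DNA `T`. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `gene_id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(gene_id = character(), seq = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("malformed FASTA: sequence data before first header (line 1)")
  rec <- cumsum(is_hdr)
  ids <- vapply(lines[is_hdr], function(h) {
    id <- strsplit(sub("^>", "", h), "\\s+")[[1]][1]
    if (is.na(id) || id == "") stop("malformed FASTA header")
    id
  }, character(1), USE.NAMES = FALSE)
  seqs <- vapply(seq_along(ids), function(k) {
    paste(lines[rec == k & !is_hdr], collapse = "")
  }, character(1))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("empty sequence for record '%s' (header at line %d)",
                 ids[which(empty)[1]], which(is_hdr)[which(empty)[1]]))
  }
  seqs <- normalize_nt(seqs)
  assert_nt(seqs, "FASTA sequence")
  tibble::tibble(gene_id = ids, seq = seqs)
}

#' Read an operon annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`, `operon_id`,
#' `position` (1 = first gene of the operon) and `utr5` (may be empty).
#'
#' @param path path to the annotation file.
#' @return A tibble with one row per gene.
#' @export
read_operon_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    operon_id = readr::col_character(),
    position = readr::col_double(),
    utr5 = readr::col_character()
  ))
  need <- c("gene_id", "operon_id", "position", "utr5")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) stop("operon table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tbl$gene_id)) {
    stop("duplicate gene_id in operon table: ",
         paste(unique(tbl$gene_id[duplicated(tbl$gene_id)]), collapse = ", "))
  }
  if (any(is.na(tbl$position)) || any(tbl$position != floor(tbl$position))) {
    stop("non-integer operon position")
  }
  if (any(tbl$position < 1)) stop("operon position must be >= 1")
  tbl$position <- as.integer(tbl$position)
  tbl$utr5 <- normalize_nt(tidyr::replace_na(tbl$utr5, ""))
  assert_nt(tbl$utr5, "utr5")
  tbl[need]
}

#' Filter CDS records down to protein-coding genes
#'
#' Applies the protein-coding rules: the sequence must start with one of
#' ATG/CTG/GTG/TTG, its length must be a positive multiple of 3, it must
#' carry no internal stop codon, and its final codon must be a stop codon.
#'
#' @param cds_records tibble with columns `gene_id` and `seq` (uppercase DNA).
#' @return A list with `kept` (tibble `gene_id`, `cds`) and `rejected`
#'   (tibble `gene_id`, `reason` with codes `BAD_START`, `BAD_LENGTH`,
#'   `INTERNAL_STOP`, `NO_TERMINAL_STOP`).
#' @export
filter_protein_coding <- function(cds_records) {
  stopifnot(all(c("gene_id", "seq") %in% names(cds_records)))
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "CTG", "GTG", "TTG")
  reason <- vapply(cds_records$seq, function(s) {
    if (!(substr(s, 1, 3) %in% starts)) return("BAD_START")
    if (nchar(s) < 6 || nchar(s) %% 3 != 0) return("BAD_LENGTH")
    codons <- split_codons(s)
    n <- length(codons)
    if (!(codons[n] %in% stops)) return("NO_TERMINAL_STOP")
    if (any(codons[-n] %in% stops)) return("INTERNAL_STOP")
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  ok <- is.na(reason)
  list(
    kept = tibble::tibble(gene_id = cds_records$gene_id[ok], cds = cds_records$seq[ok]),
    rejected = tibble::tibble(gene_id = cds_records$gene_id[!ok], reason = reason[!ok])
  )
}

#' Translate a filtered CDS to protein
#'
#' Standard bacterial genetic code; the initiator codon translates to
#' methionine whatever its identity (ATG/GTG/TTG/CTG) and the terminal stop
#' is not included.
#'
#' @param cds coding sequence that passes [filter_protein_coding()].
#' @return Amino-acid string of length `nchar(cds)/3 - 1`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  aa <- paste(seqinr::translate(seqinr::s2c(cds)), collapse = "")
  aa <- sub("\\*$", "", aa)
  paste0("M", substr(aa, 2, nchar(aa)))
}

#' Assemble gene records from filtered CDS and operon annotation
#'
#' Joins kept CDS records with the operon table, derives the protein
#' sequence, and flags first-in-operon genes. Genes absent from the
#' annotation are retained as single-gene operons with an empty 5'-UTR;
#' their UTR-dependent features will be flagged missing downstream.
#'
#' @param kept tibble `gene_id`, `cds` as returned by [filter_protein_coding()].
#' @param operon_table tibble as returned by [read_operon_table()].
#' @return A tibble of gene records: `gene_id`, `utr5`, `cds`, `protein`,
#'   `operon_id`, `position_in_operon`, `is_first_gene`.
#' @export
assemble_gene_records <- function(kept, operon_table = NULL) {
  out <- kept
  if (is.null(operon_table)) {
    out$operon_id <- out$gene_id
    out$position_in_operon <- 1L
    out$utr5 <- ""
  } else {
    out <- dplyr::left_join(out, operon_table, by = "gene_id")
    out$operon_id <- dplyr::coalesce(out$operon_id, out$gene_id)
    out$position_in_operon <- dplyr::coalesce(out$position, 1L)
    out$utr5 <- dplyr::coalesce(out$utr5, "")
    out$position <- NULL
  }
  out$protein <- vapply(out$cds, translate_cds, character(1), USE.NAMES = FALSE)
  out$is_first_gene <- out$position_in_operon == 1L
  out[, c("gene_id", "utr5", "cds", "protein", "operon_id",
          "position_in_operon", "is_first_gene")]
}
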