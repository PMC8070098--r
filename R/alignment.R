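# Alignment container and plain-text I/O.

.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-", "?")

#' Construct a gene alignment
#'
#' An aligned set of haploid amplicon sequences for one candidate gene, with
#' per-sequence accession IDs and taxon labels. Sequences are stored as an
#' n x L character matrix (one row per sequence, upper case).
#'
#' @param seqs Character vector of equal-length sequences, or an n x L
#'   character matrix.
#' @param ids Unique accession IDs, one per sequence.
#' @param taxa Optional taxon label per sequence (e.g. "acutifolius_wild",
#'   "parvifolius", "control"). Defaults to "unknown".
#' @param gene Gene name.
#' @return An object of class \code{gene_alignment}.
#' @export
gene_alignment <- function(seqs, ids = NULL, taxa = NULL, gene = "gene") {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- if (!is.null(ids)) ids[which(lens != lens[1])[1]] else which(lens != lens[1])[1]
      stop("sequences are not all the same length (first offender: ", bad, ")")
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    m <- toupper(as.matrix(seqs))
  }
  n <- nrow(m)
  if (n == 0L || ncol(m) == 0L) stop("alignment is empty")
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids must match the number of sequences")
  if (anyDuplicated(ids)) stop("duplicate sequence IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(unique(as.vector(m)), .IUPAC)
  if (length(bad)) stop("non-IUPAC characters in alignment: ",
                        paste(bad, collapse = ", "))
  if (is.null(taxa)) taxa <- rep("unknown", n)
  taxa <- as.character(taxa)
  if (length(taxa) != n) stop("taxa must match the number of sequences")
  rownames(m) <- ids
  structure(list(gene = gene, seq = m, ids = ids, taxa = taxa),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", x$gene, ": ", nrow(x$seq), " sequences x ",
      ncol(x$seq), " bp\n", sep = "")
  tt <- table(x$taxa)
  cat("  taxa: ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of sequences / alignment length
#' @param aln A \code{gene_alignment}.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln$seq)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln$seq)

#' Subset an alignment by sequence
#'
#' @param aln A \code{gene_alignment}.
#' @param which Logical, integer or character (ID) index of sequences to keep.
#' @return A \code{gene_alignment} over the selected sequences.
#' @export
subset_alignment <- function(aln, which) {
  if (is.character(which)) which <- match(which, aln$ids)
  m <- aln$seq[which, , drop = FALSE]
  gene_alignment(m, ids = aln$ids[which], taxa = aln$taxa[which], gene = aln$gene)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-FASTA of pre-aligned sequences. IDs are taken up to the
#' first whitespace; sequences are upper-cased; unequal lengths are rejected
#' (these are alignments, not raw reads).
#'
#' @param path Path to the FASTA file.
#' @param samples Optional sample sheet (data frame with \code{accession} and
#'   \code{taxon} columns, see \code{\link{read_sample_sheet}}) used to
#'   attach taxon labels.
#' @param gene Gene name; defaults to the file name without extension.
#' @return A \code{gene_alignment}.
#' @export
read_fasta <- function(path, samples = NULL, gene = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(dna))
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("sequences are not all the same length (first offender: ",
         ids[which(lens != lens[1])[1]], ")")
  m <- toupper(as.character(as.matrix(dna)))
  taxa <- NULL
  if (!is.null(samples)) {
    taxa <- samples$taxon[match(ids, samples$accession)]
    taxa[is.na(taxa)] <- "unknown"
  }
  gene_alignment(m, ids = ids, taxa = taxa, gene = gene)
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{gene_alignment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- seqs
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with header \code{accession,taxon,latitude,longitude}; the sheet is the
#' single source of taxon labels and coordinates (FASTA headers carry only
#' IDs).
#'
#' @param path Path to the CSV.
#' @return Data frame with those columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "taxon", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("duplicate accessions in sample sheet")
  df
}

#' Read a climate table
#'
#' CSV with header \code{accession,taxon,latitude,longitude,t01..t12,p01..p12}
#' (monthly mean temperatures in degrees C, precipitation totals in mm).
#'
#' @param path Path to the CSV.
#' @return Data frame suitable for \code{\link{drought_index_table}}.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "taxon", "latitude", sprintf("t%02d", 1:12),
            sprintf("p%02d", 1:12))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("climate table missing columns: ", paste(miss, collapse = ", "))
  df
}
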