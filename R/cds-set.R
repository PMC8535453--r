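# CDS containers and FASTA IO. Sequences are held as plain uppercase
# character strings; Biostrings is used only at the file boundary.

#' Construct a CDS set
#'
#' A `cds_set` holds an ordered collection of coding sequences with unique
#' identifiers, a grouping key (`gene_id`) used to collapse isoforms of the
#' same gene, and an optional label naming the genome or line.
#'
#' @param seq Character vector of nucleotide sequences. Lowercase letters
#'   are uppercased and U is mapped to T.
#' @param id Character vector of unique record identifiers.
#' @param gene_id Optional grouping key per record. By default it is parsed
#'   from `id` by stripping the suffix matched by `gene_id_pattern`.
#' @param label Optional set label (genome / line name).
#' @param gene_id_pattern Regular expression removed from `id` to obtain
#'   `gene_id`; the default strips a trailing ".N" isoform suffix.
#' @return An object of class `cds_set` with fields `id`, `gene_id`, `seq`,
#'   `length` and `label`.
#' @examples
#' x <- cds_set(c("atgtttTAA", "ATGAAATGA"), id = c("g1.1", "g2.1"))
#' x$seq
#' @export
cds_set <- function(seq, id, gene_id = NULL, label = NULL,
                    gene_id_pattern = "\\.\\d+$") {
  seq <- chartr("u", "t", as.character(seq))
  seq <- chartr("U", "T", toupper(seq))
  id <- as.character(id)
  if (length(seq) != length(id)) {
    stop("'seq' and 'id' must have the same length")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate CDS id(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(gene_id)) {
    gene_id <- sub(gene_id_pattern, "", id)
  }
  structure(
    list(id = id, gene_id = as.character(gene_id), seq = seq,
         length = nchar(seq), label = label),
    class = "cds_set"
  )
}

#' @export
print.cds_set <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("cds_set%s: %d sequence(s), length %d-%d nt\n",
              lab, length(x$id),
              if (length(x$length)) min(x$length) else 0L,
              if (length(x$length)) max(x$length) else 0L))
  invisible(x)
}

#' @export
length.cds_set <- function(x) length(x$id)

# internal positional subset preserving order
.subset_cds <- function(x, keep) {
  structure(
    list(id = x$id[keep], gene_id = x$gene_id[keep], seq = x$seq[keep],
         length = x$length[keep], label = x$label),
    class = "cds_set"
  )
}

#' Read coding sequences from a FASTA file
#'
#' Records keep their file order; sequences are uppercased with U mapped to
#' T. The record id is the first whitespace-delimited token of the header.
#'
#' @param path Path to a (multi-)FASTA file.
#' @param label Optional set label; defaults to the file name.
#' @param gene_id_pattern Passed to [cds_set()] to derive the gene grouping
#'   key from record ids.
#' @return A [cds_set()].
#' @export
read_cds_fasta <- function(path, label = NULL,
                           gene_id_pattern = "\\.\\d+$") {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  # BStringSet: tolerate lowercase and RNA letters, normalized by cds_set()
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(label)) {
    label <- basename(path)
  }
  cds_set(as.character(ss), id = ids, label = label,
          gene_id_pattern = gene_id_pattern)
}

#' Write a CDS set to FASTA
#'
#' @param x A [cds_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cds_fasta <- function(x, path) {
  stopifnot(inherits(x, "cds_set"))
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
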