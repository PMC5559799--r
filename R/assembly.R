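#' Assembly container
#'
#' An `assembly_set` holds the contigs of one transcriptome assembly as a
#' named character vector of uppercase DNA sequences plus a label identifying
#' the assembly (assembler / k-mer tag).  Iteration order is the input order
#' and is preserved by every operation in the package.
#'
#' @param seqs named character vector; names are contig ids, values are DNA
#'   sequences over A/C/G/T/N (uppercased on construction).
#' @param label single character string tagging the assembly.
#' @return an object of class `assembly_set`.
#' @examples
#' asm <- assembly_set(c(c1 = "ACGT", c2 = "GGGTTT"), label = "demo")
#' n_contigs(asm)
#' contig_lengths(asm)
#' @export
assembly_set <- function(seqs, label = "assembly") {
  if (is.null(names(seqs)) && length(seqs) > 0)
    stop_("contigs must be named")
  ids <- names(seqs) %||% character(0)
  seqs <- setNames(toupper(as.character(seqs)), ids)
  if (length(ids) && any(!nzchar(ids)))
    stop_("contig ids must be nonempty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_("duplicate contig id: %s", dup[[1]])
  if (length(seqs) && any(nchar(seqs) == 0))
    stop_("empty sequence for contig: %s", ids[nchar(seqs) == 0][[1]])
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    pos <- regexpr("[^ACGTN]", seqs[[bad[[1]]]])
    stop_("non-IUPAC character in contig %s at position %d", ids[bad[[1]]], pos)
  }
  structure(list(label = as.character(label), seqs = seqs),
            class = "assembly_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname assembly_set
#' @param x an `assembly_set`.
#' @export
n_contigs <- function(x) {
  stopifnot(inherits(x, "assembly_set"))
  length(x$seqs)
}

#' @rdname assembly_set
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "assembly_set"))
  nchar(x$seqs)
}

#' @rdname assembly_set
#' @export
contig_ids <- function(x) {
  stopifnot(inherits(x, "assembly_set"))
  names(x$seqs)
}

#' @export
print.assembly_set <- function(x, ...) {
  cat(sprintf("<assembly_set '%s': %d contigs, %s bases>\n",
              x$label, n_contigs(x),
              format(sum(contig_lengths(x)), big.mark = ",")))
  invisible(x)
}

#' @export
length.assembly_set <- function(x) length(x$seqs)
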