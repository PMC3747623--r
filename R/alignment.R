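#' Define the species roster of a population alignment
#'
#' The roster names the focal population sequences (e.g. 37 resequenced
#' genomes), the outgroup sequences used to polarize ancestral states (at
#' least two, which must all agree for a call), and the reference sequence
#' that carries genome coordinates.
#'
#' @param focal Character vector of focal sequence names.
#' @param outgroups Character vector of >= 2 outgroup sequence names.
#' @param reference Name of the reference sequence; defaults to the first
#'   focal name.
#' @return An object of class `species_roster`.
#' @export
species_roster <- function(focal, outgroups, reference = focal[[1]]) {
  if (length(outgroups) < 2) abort_ctx("at least 2 outgroups are required for polarization")
  if (length(intersect(focal, outgroups)) > 0) {
    abort_ctx("focal and outgroup sets must be disjoint (shared: %s)",
      paste(intersect(focal, outgroups), collapse = ", "))
  }
  structure(
    list(focal = focal, outgroups = outgroups, reference = reference),
    class = "species_roster"
  )
}

#' @export
print.species_roster <- function(x, ...) {
  cat("<species_roster> ", length(x$focal), " focal, ",
    length(x$outgroups), " outgroups, reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

new_block <- function(text, start, chrom, id) {
  widths <- unique(nchar(text))
  if (length(widths) != 1) abort_ctx("alignment rows have unequal lengths in block %s", id)
  structure(
    list(id = id, text = text, start = start, chrom = chrom, width = widths),
    class = "aln_block"
  )
}

#' @export
print.aln_block <- function(x, ...) {
  cat("<aln_block> ", x$id, ": ", length(x$text), " rows x ", x$width,
    " columns (", x$chrom, ":", x$start, ")\n", sep = "")
  invisible(x)
}

maf_src_name <- function(src) sub("\\..*$", "", src)

#' Read alignment blocks from a MAF file
#'
#' Parses the `a`/`s` block structure of a Multiple Alignment Format file.
#' Row names are matched against the roster either as the full `src` field
#' or as its database prefix (the part before the first dot), so
#' `dm3.chr2L` matches a roster name `dm3`. If the reference row is on the
#' minus strand the whole block is reverse-complemented onto the reference
#' plus strand, so all downstream word logic sees one consistent strand.
#' Roster species missing from a block are simply absent from its rows;
#' filters downstream treat absence as non-callable.
#'
#' @param path Path to a MAF file.
#' @param roster Optional [species_roster()]; when given, rows are restricted
#'   to roster names and a warning is raised for roster names never seen.
#' @return A list of `aln_block` objects, in file order.
#' @export
read_maf <- function(path, roster = NULL) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, n) {
    if (is.null(cur) || length(cur$text) == 0) return(NULL)
    ref_name <- if (!is.null(roster)) roster$reference else names(cur$text)[[1]]
    i <- match(ref_name, names(cur$text))
    if (is.na(i)) i <- 1L
    if (cur$strand[[i]] == "-") {
      # flip the block onto the reference plus strand
      cur$text <- vapply(cur$text, revcomp_string, character(1))
      cur$start[[i]] <- cur$src_size[[i]] - (cur$start[[i]] + cur$size[[i]])
    }
    new_block(cur$text, cur$start[[i]], cur$chrom[[i]], id = n)
  }
  seen <- character(0)
  n_blocks <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (startsWith(line, "a")) {
      b <- flush(cur, n_blocks + 1L)
      if (!is.null(b)) {
        blocks[[length(blocks) + 1L]] <- b
        n_blocks <- n_blocks + 1L
      }
      cur <- list(text = character(0), start = integer(0), size = integer(0),
        strand = character(0), src_size = integer(0), chrom = character(0))
    } else if (startsWith(line, "s")) {
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) != 7 || is.null(cur)) {
        abort_ctx("malformed MAF 's' line at line %d of %s", ln, path)
      }
      name <- maf_src_name(f[[2]])
      seen <- union(seen, name)
      if (!is.null(roster) &&
        !(name %in% c(roster$focal, roster$outgroups, roster$reference))) {
        next
      }
      cur$text[[name]] <- toupper(f[[7]])
      cur$start[[name]] <- as.integer(f[[3]])
      cur$size[[name]] <- as.integer(f[[4]])
      cur$strand[[name]] <- f[[5]]
      cur$src_size[[name]] <- as.integer(f[[6]])
      cur$chrom[[name]] <- sub("^[^.]*\\.?", "", f[[2]])
    }
  }
  b <- flush(cur, n_blocks + 1L)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  if (!is.null(roster)) {
    missing <- setdiff(c(roster$focal, roster$outgroups), seen)
    if (length(missing) > 0 && length(blocks) > 0) {
      rlang::warn(paste0("roster names never seen in ", path, ": ",
        paste(missing, collapse = ", ")))
    }
  }
  blocks
}

#' Read and write aligned FASTA
#'
#' An aligned FASTA holds one equal-length gapped record per genome; it is
#' the native output of the simulator and a convenient desk-scale alternative
#' to MAF. Reading produces a single alignment block starting at reference
#' coordinate 0.
#'
#' @param path File path.
#' @param chrom Sequence name recorded for the block (default `"chr"`).
#' @return `read_aligned_fasta()`: a list holding one `aln_block`.
#' @export
read_aligned_fasta <- function(path, chrom = "chr") {
  set <- Biostrings::readBStringSet(path)
  text <- toupper(as.character(set))
  start <- stats::setNames(rep(0L, length(text)), names(text))
  list(new_block(text, 0L, chrom, id = 1L))
}

#' @rdname read_aligned_fasta
#' @param x Named character vector of equal-length aligned sequences, or an
#'   `aln_block`.
#' @export
write_aligned_fasta <- function(x, path) {
  if (inherits(x, "aln_block")) x <- x$text
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}

block_matrix <- function(block, names = NULL) {
  text <- block$text
  if (!is.null(names)) {
    text <- text[intersect(names, names(text))]
  }
  if (length(text) == 0) {
    return(matrix(character(0), nrow = 0, ncol = block$width))
  }
  m <- do.call(rbind, strsplit(unname(text), ""))
  rownames(m) <- names(text)
  toupper(m)
}

ref_coordinates <- function(block, reference) {
  ref <- block$text[[reference]]
  if (is.null(ref)) return(rep(NA_integer_, block$width))
  sym <- strsplit(ref, "")[[1]]
  pos <- block$start + cumsum(sym != "-") - 1L
  pos[sym == "-"] <- NA_integer_
  as.integer(pos)
}

#' Per-column view of an alignment block
#'
#' Expands a block into one row per alignment column, with the reference
#' coordinate (0-based; `NA` at reference-gap columns, where no new
#' reference position is consumed) and one column of symbols per sequence.
#' Symbols are uppercased; gaps (`-`) and ambiguity codes (`N`, ...) pass
#' through unchanged for downstream filters to see.
#'
#' @param block An `aln_block`.
#' @param roster Optional [species_roster()] used to pick the reference row
#'   and restrict/order the sequence columns.
#' @return A tibble with `col` (1-based alignment column), `ref_pos0` and one
#'   character column per sequence.
#' @export
alignment_columns <- function(block, roster = NULL) {
  ref_name <- if (!is.null(roster)) roster$reference else names(block$text)[[1]]
  keep <- if (!is.null(roster)) {
    intersect(unique(c(roster$focal, roster$outgroups, roster$reference)), names(block$text))
  } else {
    names(block$text)
  }
  m <- block_matrix(block, keep)
  out <- tibble::tibble(
    col = seq_len(block$width),
    ref_pos0 = ref_coordinates(block, ref_name)
  )
  for (nm in rownames(m)) out[[nm]] <- m[nm, ]
  out
}
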