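DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

`%||%` <- rlang::`%||%`

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

abort_ctx <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "contextmut_error")
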