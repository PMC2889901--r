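# small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# random DNA with a given GC fraction
.random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# AT-alternation pad of length n, starting with A
.at_pad <- function(n) {
  if (n <= 0) return("")
  substr(strrep("AT", ceiling(n / 2)), 1L, n)
}

.has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

.join_flags <- function(flags) paste(flags, collapse = ",")

.stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "splicearray_error")))
}
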