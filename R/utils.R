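# rbind a list of data.frames, tolerating NULL elements and empty lists
rbind_all <- function(lst, template = NULL) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(template)
  out <- do.call(rbind, lst)
  row.names(out) <- NULL
  out
}

empty_intervals <- function()
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
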