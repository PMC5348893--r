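withr_local_file <- function(name) {
  tempfile(pattern = sub("\\..*$", "", name),
           fileext = sub("^[^.]*", "", name))
}

mutate_dna <- function(x, rate) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
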