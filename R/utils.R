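# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# compact string key for deduplicating canonical partitions
partition_key <- function(z) paste(as.integer(z), collapse = ",")
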