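# Generates inst/extdata/espf_vocab_synthetic.txt: a 2586-entry SMILES
# subword vocabulary in the style of the explainable substructure
# partition fingerprint (frequency-ranked subwords over tokenized SMILES).
# Synthetic: derived from the packaged drug SMILES corpus rather than the
# published large-scale vocabulary, which is not redistributed here.
# Entries are token sequences joined by a single space.

tokenize <- function(smiles) {
  regmatches(smiles, gregexpr(
    "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|.", smiles))[[1]]
}

d <- read.delim("inst/extdata/drug_smiles.tsv", header = TRUE)
counts <- new.env(hash = TRUE)
for (s in d$smiles) {
  toks <- tokenize(s)
  n <- length(toks)
  for (len in 1:10) {
    if (n < len) break
    for (i in seq_len(n - len + 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
}
keys <- ls(counts)
freq <- vapply(keys, function(k) counts[[k]], integer(1))
ord <- order(-freq, nchar(keys), keys)
vocab <- keys[ord]
# subwords seen at least twice rank first; single characters always kept
vocab <- vocab[freq[ord] >= 2 | !grepl(" ", vocab)]
stopifnot(length(vocab) >= 2586)
vocab <- vocab[seq_len(2586)]
writeLines(c("# synthetic SMILES subword vocabulary, version 1.0", vocab),
           "inst/extdata/espf_vocab_synthetic.txt")
cat("wrote", length(vocab), "subwords,",
    file.size("inst/extdata/espf_vocab_synthetic.txt"), "bytes\n")
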