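# Shared constants; file name sorts first so these exist when the other
# sources are evaluated.

# IUPAC genotype codes used throughout: a called base encodes an unordered
# diploid genotype; ambiguity letters are heterozygotes, '-' is a gap and
# 'N' an uncalled site.
.IUPAC_ALLELES <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C")
)

.IUPAC_CARRIES <- lapply(.IUPAC_ALLELES, unique)

.HET_CODES <- c("R", "Y", "S", "W", "K", "M")

# integer-coded alleles per IUPAC genotype: two rows (allele 1, allele 2)
.ALLELE_CODE <- local({
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(NA_integer_, nrow = 2L, ncol = length(.IUPAC_ALLELES),
              dimnames = list(NULL, names(.IUPAC_ALLELES)))
  for (b in names(.IUPAC_ALLELES)) m[, b] <- code[.IUPAC_ALLELES[[b]]]
  m
})

.pkg_cache <- new.env(parent = emptyenv())
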