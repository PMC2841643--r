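#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist hclust kmeans median prcomp rbinom rnorm rpois
#'   runif sd setNames cutree
#' @importFrom utils read.table write.table head tail
NULL

# Stable 32-bit string hash (polynomial rolling hash), used to fan a single
# pipeline seed out into independent per-stage seeds.
.hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a child seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' run seed plus a stage name, so stages can be re-run in isolation and adding
#' a stage never perturbs the randomness of another.
#'
#' @param seed Integer master seed.
#' @param tag Character stage tag, e.g. `"reads/sampleA"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  as.integer((abs(seed) %% 2147483647 * 7919 + .hash_string(tag)) %% 2147483647)
}

.assert <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq A single character string over `{A,C,G,T,N}`.
#' @return The reverse complement, same case.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# fraction of G+C among A/C/G/T characters (N ignored)
.gc_fraction <- function(seq) {
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) return(NA_real_)
  sum(counts[intersect(names(counts), c("G", "C"))]) / acgt
}
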