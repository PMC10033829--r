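# Shared fixtures, all built in code.

# Ten-probe manifest exercising every filter rule twice.
toy_manifest <- function() {
  ids <- c("cg0001", "cg0002", "cg0003", "cg0004",
           "ch.1.123", "ch.2.456",
           "cg0005", "cg0006",
           "cg0007", "cg0008")
  chrom <- c("chr1", "chr2", "chr3", "chr4",
             "chr1", "chrX",          # the chrX ch. probe counts under ch only
             "chrX", "Y",
             "chr5", "chr6")
  vals <- matrix(seq_len(length(ids) * 3) / 100, nrow = length(ids),
                 dimnames = list(ids, c("s1", "s2", "s3")))
  methylation_matrix(vals, chrom = chrom, pos = seq_along(ids) * 100L,
                     scale = "beta")
}

toy_blacklist <- function() c("cg0007", "cg0008")

# Five-gene annotation plus eight probes with hand-enumerated membership:
# A: p1, p2; B: p2, p3; C: p5; D: p6, p7; E: p6.  p4 and p8 map nowhere.
toy_annotation <- function() {
  data.frame(gene = c("A", "B", "C", "D", "E"),
             chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
             strand = c("+", "-", "+", "+", "-"),
             start = c(1000L, 1500L, 5000L, 1000L, 100L),
             end = c(2000L, 2500L, 6000L, 2000L, 300L),
             stringsAsFactors = FALSE)
}

toy_probes_matrix <- function() {
  ids <- paste0("p", 1:8)
  chrom <- c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2")
  pos <- c(700L, 1600L, 2900L, 4400L, 5500L, 700L, 900L, 2100L)
  vals <- matrix(stats::rnorm(8 * 4), nrow = 8,
                 dimnames = list(ids, paste0("s", 1:4)))
  methylation_matrix(vals, chrom = chrom, pos = pos, scale = "M")
}

# Small null dataset for the association tests: binary X confounded with C.
null_testbed <- function(n = 150, K = 6, seed = 101) {
  set.seed(seed)
  C <- cbind(age = stats::rnorm(n), bmi = stats::rnorm(n))
  X <- stats::rbinom(n, 1, stats::plogis(0.3 * C[, 1]))
  M <- matrix(stats::rnorm(n * K), n, K)
  Y <- 0.4 * C[, 1] + stats::rnorm(n)
  list(X = X, C = C, M = M, Y = Y)
}

# Monte-Carlo tail probability of sum(lambda * chisq_1) above q.
mc_tail <- function(lambdas, q, n = 1e6) {
  s <- numeric(n)
  for (l in lambdas) s <- s + l * stats::rchisq(n, 1)
  mean(s > q)
}
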