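# Doubled-haploid genome and genotype simulation.
#
# DH lines are fully homozygous, so each marker locus is coded -1/+1
# (Cockerham scaling for a biallelic homozygous population). A line is one
# recombinant gamete: within a chromosome the codes form a two-state Markov
# chain whose switch probability between adjacent markers is the Haldane
# recombination fraction at the inter-marker map distance; chromosomes
# assort independently.

#' Specify a simulated genome
#'
#' The genome has `n_chromosomes` chromosomes of equal genetic length with
#' markers equally spaced within each chromosome. When `n_markers` is not a
#' multiple of `n_chromosomes`, the `remainder` policy either distributes
#' the extra markers over the first chromosomes (`"distribute"`, default) or
#' rejects the configuration (`"strict"`).
#'
#' @param n_markers total number of marker loci across the genome.
#' @param n_chromosomes number of chromosomes (default 10).
#' @param map_length genetic length of every chromosome, in Morgans
#'   (default 1).
#' @param remainder `"distribute"` or `"strict"`; see Details.
#' @return an object of class `genome_spec` with the marker map
#'   (`marker`, `chromosome`, `position` in Morgans).
#' @examples
#' gs <- genome_spec(100)
#' table(gs$map$chromosome)  # 10 markers on each of 10 chromosomes
#' @export
genome_spec <- function(n_markers, n_chromosomes = 10L, map_length = 1,
                        remainder = c("distribute", "strict")) {
  remainder <- match.arg(remainder)
  if (n_markers < 1 || n_chromosomes < 1 || map_length <= 0)
    stop_config("n_markers and n_chromosomes must be positive and map_length > 0")
  n_markers <- as.integer(n_markers)
  n_chromosomes <- as.integer(n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra != 0L && remainder == "strict")
    stop_config("n_markers (%d) is not divisible by n_chromosomes (%d)",
                n_markers, n_chromosomes)
  per_chr <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  if (extra > 0L) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  if (any(per_chr < 1L))
    stop_config("every chromosome must carry at least one marker")
  pos <- unlist(lapply(per_chr, function(k) {
    if (k == 1L) 0 else seq(0, map_length, length.out = k)
  }))
  map <- data.frame(
    marker = paste0("M", seq_len(n_markers)),
    chromosome = rep(seq_len(n_chromosomes), per_chr),
    position = pos
  )
  structure(
    list(n_markers = n_markers, n_chromosomes = n_chromosomes,
         map_length = map_length, markers_per_chromosome = per_chr,
         map = map),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("Genome: %d chromosomes, %d markers, %.2f Morgans each\n",
              x$n_chromosomes, x$n_markers, x$map_length))
  invisible(x)
}

# Haldane map function: recombination fraction at map distance d (Morgans).
haldane <- function(d) (1 - exp(-2 * d)) / 2

#' Simulate doubled-haploid genotypes
#'
#' Each line is an independent recombinant gamete, doubled: codes are -1/+1
#' with no heterozygotes and no missing values. The first marker of every
#' chromosome is -1 or +1 with probability 1/2; adjacent markers recombine
#' with the Haldane frequency `r = (1 - exp(-2d))/2` at the inter-marker
#' distance `d = map_length / (markers_per_chromosome - 1)`.
#'
#' @param spec a [genome_spec()].
#' @param n number of DH lines to simulate.
#' @param seed integer seed; identical `(spec, n, seed)` give bit-identical
#'   matrices.
#' @return an object of class `dh_pop`: `genotypes` (`n x m` matrix of
#'   -1/+1), the marker `map`, `qtl_indices` (unset; see [place_qtl()]) and
#'   the `seed`.
#' @examples
#' pop <- simulate_dh_genotypes(genome_spec(20, 2), n = 5, seed = 1)
#' all(pop$genotypes %in% c(-1, 1))
#' @export
simulate_dh_genotypes <- function(spec, n, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  if (n < 1) stop_config("n must be a positive number of lines")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  blocks <- lapply(seq_len(spec$n_chromosomes), function(ci) {
    k <- spec$markers_per_chromosome[ci]
    G <- matrix(0, n, k)
    G[, 1] <- sample(c(-1, 1), n, replace = TRUE)
    if (k > 1L) {
      r <- haldane(spec$map_length / (k - 1))
      for (j in 2:k) {
        flip <- stats::runif(n) < r
        G[, j] <- ifelse(flip, -G[, j - 1], G[, j - 1])
      }
    }
    G
  })
  genotypes <- do.call(cbind, blocks)
  dimnames(genotypes) <- list(paste0("L", seq_len(n)), spec$map$marker)
  structure(
    list(genotypes = genotypes, map = spec$map, spec = spec,
         qtl_indices = NULL, seed = as.integer(seed)),
    class = "dh_pop"
  )
}

#' Place QTL at marker loci
#'
#' QTL are constrained to marker positions (`q <= m`). Under
#' `"evenly_spaced"` placement the indices are deterministic and spread
#' uniformly across the genome; under `"random"` they are a uniform sample
#' without replacement, sorted into genome order.
#'
#' @param pop a `dh_pop`.
#' @param q number of QTL, `1 <= q <= m`.
#' @param rule placement rule.
#' @param seed required for `"random"` placement.
#' @return the population with `qtl_indices` set.
#' @examples
#' pop <- simulate_dh_genotypes(genome_spec(10, 1), 4, seed = 1)
#' place_qtl(pop, 5)$qtl_indices  # 1 3 5 7 9
#' @export
place_qtl <- function(pop, q, rule = c("evenly_spaced", "random"),
                      seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(pop, "dh_pop"))
  m <- ncol(pop$genotypes)
  if (q < 1 || q > m)
    stop_config("q must satisfy 1 <= q <= m (got q = %s, m = %d)", q, m)
  q <- as.integer(q)
  if (rule == "evenly_spaced") {
    idx <- floor((seq_len(q) - 1) * m / q) + 1L
  } else {
    if (is.null(seed)) stop_config("random placement requires a seed")
    set.seed(as.integer(seed))
    idx <- sort(sample.int(m, q))
  }
  pop$qtl_indices <- as.integer(idx)
  pop
}

#' @export
print.dh_pop <- function(x, ...) {
  cat(sprintf("DH population: %d lines x %d markers (%d chromosomes)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$spec$n_chromosomes))
  if (!is.null(x$qtl_indices))
    cat(sprintf("  %d QTL at marker loci\n", length(x$qtl_indices)))
  invisible(x)
}

#' Export genotypes and marker map
#'
#' Writes the line-by-marker code matrix as CSV and, optionally, the marker
#' map (`marker`, `chromosome`, `position_cM`). `write_plink` produces a
#' minimal PLINK-style .ped/.map pair (codes -1/+1 mapped to alleles A/B)
#' for interoperability.
#'
#' @param pop a `dh_pop`.
#' @param file output path for the genotype CSV.
#' @param map_file optional path for the marker map CSV.
#' @return invisibly, the genotype path.
#' @export
write_genotypes <- function(pop, file, map_file = NULL) {
  stopifnot(inherits(pop, "dh_pop"))
  utils::write.csv(as.data.frame(pop$genotypes), file, row.names = TRUE)
  if (!is.null(map_file)) {
    mp <- pop$map
    mp$position_cM <- mp$position * 100
    utils::write.csv(mp[, c("marker", "chromosome", "position_cM")],
                     map_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_genotypes
#' @param prefix path prefix for `<prefix>.ped` and `<prefix>.map`.
#' @export
write_plink <- function(pop, prefix) {
  stopifnot(inherits(pop, "dh_pop"))
  al <- ifelse(pop$genotypes > 0, "A", "B")
  ped <- cbind(rownames(pop$genotypes), rownames(pop$genotypes),
               0, 0, 0, -9,
               al[, rep(seq_len(ncol(al)), each = 2)])
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mp <- data.frame(pop$map$chromosome, pop$map$marker, 0,
                   round(pop$map$position * 100))
  utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
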