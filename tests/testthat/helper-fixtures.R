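# Shared fixtures: all constructed programmatically, no stored data.

# Wrap a bare code matrix as a dh_pop (one chromosome unless stated),
# for direct control over genotypes in incidence-matrix tests.
manual_pop <- function(genotypes, chromosome = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  chromosome <- chromosome %||% rep(1L, m)
  colnames(genotypes) <- paste0("M", seq_len(m))
  rownames(genotypes) <- paste0("L", seq_len(n))
  map <- data.frame(marker = colnames(genotypes),
                    chromosome = chromosome,
                    position = stats::ave(rep(0, m), chromosome,
                                          FUN = seq_along) - 1)
  spec <- list(n_markers = m, n_chromosomes = length(unique(chromosome)),
               map_length = 1,
               markers_per_chromosome = as.integer(table(chromosome)),
               map = map)
  class(spec) <- "genome_spec"
  structure(list(genotypes = genotypes, map = map, spec = spec,
                 qtl_indices = NULL, seed = NA_integer_),
            class = "dh_pop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reported first-order coefficient vectors used by the ascent stage.
svm_minus_blup_fit <- function() {
  first_order_fit(c("(Intercept)" = -0.130, ind = 0.019, m = -0.004,
                    qtl = -0.003, epi = 0.043, h = 0.020),
                  response_name = "rSVM-rBLUP")
}

blup_fit <- function() {
  first_order_fit(c("(Intercept)" = 0.462, ind = 0.039, m = -0.005,
                    qtl = 0.025, epi = -0.285, h = 0.144),
                  response_name = "rBLUP")
}

# The 16 treatment combinations of the half-fractional factorial over the
# starting region (ind, m, qtl, epi, h), natural units.
half_fraction_treatments <- function() {
  txt <- "
1000 400 100 0.2 0.5
 200 100 100 0.2 0.5
 200 400  10 0.2 0.5
1000 100  10 0.2 0.5
 200 400 100 0.5 0.5
1000 100 100 0.5 0.5
1000 400  10 0.5 0.5
 200 100  10 0.5 0.5
 200 400 100 0.2 0.2
1000 100 100 0.2 0.2
1000 400  10 0.2 0.2
 200 100  10 0.2 0.2
1000 400 100 0.5 0.2
 200 100 100 0.5 0.2
 200 400  10 0.5 0.2
1000 100  10 0.5 0.2"
  out <- read.table(text = txt,
                    col.names = c("ind", "m", "qtl", "epi", "h"))
  out
}
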