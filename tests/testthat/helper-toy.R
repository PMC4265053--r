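# Shared fixtures: all generated in code.

TEST_CDS <- "AUGGCUAGCAAAGGAGAAGAACUUUUCACUGGAGUUGUCCCAAUU"

test_context <- function(rbs = random_rbs(35), organism = "E. coli") {
  mrna_context(rbs = rbs, cds = TEST_CDS, organism = organism)
}

# Position-additive toy rate model: each (base, position) contributes a fixed
# free energy; rate = 2500 * exp(-0.45 * sum). Gives a fully known,
# enumerable design landscape for GA-vs-brute-force comparisons.
additive_rate_fn <- function(energy_matrix, beta = 0.45, scale = 2500) {
  bases <- c("A", "C", "G", "U")
  stopifnot(nrow(energy_matrix) == 4)
  function(variants) {
    vapply(variants, function(v) {
      s <- strsplit(v, "")[[1]]
      dg <- sum(energy_matrix[cbind(match(s, bases), seq_along(s))])
      scale * exp(-beta * dg)
    }, numeric(1))
  }
}

# deterministic energy matrix spanning several decades over a length-3 space
toy_energy_matrix <- function(L = 3L) {
  base_levels <- c(A = 0, C = -2.5, G = -5, U = -7.5)
  m <- matrix(rep(base_levels, L), nrow = 4)
  sweep(m, 2, (seq_len(L) - 1) * 0.8, `+`)
}

# Greedy coordinate ascent over the three RBS sequences: repeatedly accept
# the single nucleotide substitution (any gene, any position) that most
# improves predicted productivity, until no substitution improves it. The
# result is a local optimum of the composed sequence -> expression ->
# activity map under single-mutation moves.
ascend_rbs_productivity <- function(sm, ctxs, rbs3, engine,
                                    model = ribosome_model(),
                                    max_passes = 40L) {
  rate_cache <- new_rate_cache()
  gene_rate <- function(g, seq) {
    seamapr:::predict_one_variant(seq, ctxs[[g]], model, engine,
                                  rate_cache)$rate_au
  }
  prod_cache <- new.env(parent = emptyenv())
  prod_of <- function(rates) {
    key <- paste(signif(rates, 12), collapse = "|")
    hit <- prod_cache[[key]]
    if (is.null(hit)) {
      hit <- predict_productivity(sm, pathway_variant(rates))
      prod_cache[[key]] <- hit
    }
    hit
  }
  rates <- vapply(1:3, function(g) gene_rate(g, rbs3[g]), numeric(1))
  best_prod <- prod_of(rates)
  bases <- c("A", "C", "G", "U")
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    best_move <- NULL
    for (g in 1:3) {
      for (p in 1:35) {
        old <- substr(rbs3[g], p, p)
        for (b in setdiff(bases, old)) {
          cand <- rbs3[g]
          substr(cand, p, p) <- b
          r_new <- rates
          r_new[g] <- gene_rate(g, cand)
          if (r_new[g] == rates[g]) next  # rate-neutral substitution
          pr <- prod_of(r_new)
          if (pr > best_prod * (1 + 1e-9)) {
            best_prod <- pr
            best_move <- list(g = g, cand = cand, rates = r_new)
          }
        }
      }
    }
    if (is.null(best_move)) break
    rbs3[best_move$g] <- best_move$cand
    rates <- best_move$rates
    improved <- TRUE
  }
  rbs3
}

# Independent brute-force oracle over every degenerate sequence of length L:
# coverage computed by direct interval checks, objective by direct formula.
brute_force_design_optimum <- function(L, rate_fn, r_min, r_max, W,
                                       penalty = 0.02) {
  alphabet <- c("A", "C", "G", "U", "W", "S", "M", "K", "R", "Y",
                "B", "D", "H", "V", "N")
  dseqs <- ""
  for (i in seq_len(L)) dseqs <- as.vector(outer(dseqs, alphabet, paste0))
  B <- ceiling(round(log10(r_max / r_min) / W, 9))
  centers <- r_min * 10^(W * (seq_len(B) - 0.5))
  best <- -Inf
  best_dseq <- NULL
  for (d in dseqs) {
    variants <- expand_dseq(d)
    rates <- rate_fn(variants)
    filled <- vapply(centers, function(y) {
      any(rates >= y / 10^W & rates <= y * 10^W)
    }, logical(1))
    f <- sum(filled) / B - penalty * length(variants)
    if (f > best + 1e-12) {
      best <- f
      best_dseq <- d
    }
  }
  list(objective = best, dseq = best_dseq, B_total = B)
}
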