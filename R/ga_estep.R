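# Genetic-algorithm E-step: for fixed quadratic coefficients, search
# the mutable assignment bits of one mini-batch subset so that the
# subset's sum of squared residuals is minimized. The chromosome is the
# vector of mutable candidate cells (isoforms in subset order, each
# contributing its candidate terms in GO-id order); frozen bits
# contribute to shared-term counts but are never searched.

#' GA hyper-parameters
#'
#' Crossover probability 0.8 with an additional 0.1 per-bit mutation
#' probability, rank-proportional selection and single-individual
#' elitism; population size and generation count default to 50.
#'
#' @param population_size population size (>= 2).
#' @param generations number of generations.
#' @param crossover_prob probability that a selected parent pair is
#'   recombined (uniform crossover) rather than copied.
#' @param mutation_prob per-bit flip probability applied after
#'   crossover (and when seeding the initial population).
#' @param elitism_count number of best individuals copied unchanged
#'   into the next generation.
#' @param seed optional integer seed; when `NULL` the current RNG
#'   stream is used.
#' @return object of class `ga_params`.
#' @export
ga_params <- function(population_size = 50L, generations = 50L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism_count = 1L, seed = NULL) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism_count >= 1L, elitism_count < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 seed = seed),
            class = "ga_params")
}

#' Build the E-step search problem for one isoform subset
#'
#' @param assignment an [assignment_matrix()].
#' @param subset character vector of isoform ids in the batch.
#' @param pairs scored pairs within the subset: data.frame with columns
#'   `a`, `b`, `std`.
#' @param model a [quadratic_model()].
#' @return object of class `subset_problem` with the chromosome layout
#'   (`mut`), the fixed base bits, and the pair structure.
#' @export
subset_problem <- function(assignment, subset, pairs, model) {
  stopifnot(inherits(assignment, "assignment_matrix"),
            inherits(model, "quadratic_model"))
  rows <- match(subset, assignment$isoforms)
  if (anyNA(rows)) {
    .stop_typed("isoformGO_model_error", "subset isoform not in assignment")
  }
  base <- assignment$bits[rows, , drop = FALSE]
  cand <- assignment$candidate[rows, , drop = FALSE] &
    !assignment$frozen[rows, , drop = FALSE]
  # keep only columns that can matter to this subset
  keep <- which(colSums(cand | base) > 0L)
  base <- base[, keep, drop = FALSE]
  cand <- cand[, keep, drop = FALSE]
  # chromosome layout: subset order x term (GO-id) order, row by row
  mut <- which(t(cand), arr.ind = TRUE)  # t(): row-major enumeration
  mut <- cbind(row = unname(mut[, 2L]), col = unname(mut[, 1L]))
  dimnames(mut) <- list(NULL, c("row", "col"))
  structure(list(isoforms = subset,
                 terms = assignment$terms[keep],
                 base = base,
                 mut = mut,
                 pi = match(pairs$a, subset),
                 pj = match(pairs$b, subset),
                 std = pairs$std,
                 model = model),
            class = "subset_problem")
}

#' Encode the current assignment of a subset as a chromosome
#'
#' @param assignment an [assignment_matrix()].
#' @param problem a [subset_problem()].
#' @return logical vector of mutable bits; `decode_bits(encode(...))`
#'   reproduces the subset rows of the matrix.
#' @export
encode <- function(assignment, problem) {
  rows <- match(problem$isoforms, assignment$isoforms)
  bits <- assignment$bits[rows, problem$terms, drop = FALSE]
  unname(bits[problem$mut])
}

#' Decode a chromosome into the subset's full bit matrix
#'
#' @param bits logical chromosome.
#' @param problem a [subset_problem()].
#' @return logical matrix (subset isoforms by problem terms): the
#'   frozen/base bits with the mutable cells replaced by `bits`.
#' @export
decode_bits <- function(bits, problem) {
  stopifnot(length(bits) == nrow(problem$mut))
  B <- problem$base
  B[problem$mut] <- bits
  B
}

.subset_ssr <- function(B, problem) {
  storage.mode(B) <- "integer"
  tau <- tcrossprod(B)[cbind(problem$pi, problem$pj)]
  b <- problem$model$beta
  mu <- b[["beta2"]] * tau^2 + b[["beta1"]] * tau + b[["beta0"]]
  sum((mu - problem$std)^2)
}

#' Fitness of a chromosome: negated subset sum of squared residuals
#'
#' Maximizing this fitness minimizes the least-squares objective on the
#' subset's pairs, shared-term counts being recomputed from the decoded
#' bits (mutable plus frozen).
#'
#' @param bits logical chromosome.
#' @param problem a [subset_problem()].
#' @return scalar fitness (higher is better; 0 is a perfect fit).
#' @export
fitness <- function(bits, problem) {
  -.subset_ssr(decode_bits(bits, problem), problem)
}

#' Run the genetic algorithm on one subset problem
#'
#' The initial population is the current assignment plus mutated copies
#' of it. Each generation: rank-proportional roulette selection
#' (selection probability proportional to the individual's rank in
#' increasing fitness order), uniform crossover with probability
#' `crossover_prob`, per-bit mutation at `mutation_prob`, and the elite
#' individual(s) carried unchanged — so the best fitness trace is
#' non-decreasing and the result is never worse than the initial
#' assignment.
#'
#' @param problem a [subset_problem()].
#' @param params a [ga_params()].
#' @param init logical chromosome to start from (the current
#'   assignment's encoding).
#' @return list with `bits` (best chromosome), `fitness` (its fitness)
#'   and `trace` (best fitness per generation, element 1 being the
#'   initial population).
#' @export
evolve <- function(problem, params = ga_params(), init = NULL) {
  init <- init %||% unname(problem$base[problem$mut])
  k <- nrow(problem$mut)
  stopifnot(length(init) == k)
  if (k == 0L) {
    return(list(bits = init, fitness = fitness(init, problem), trace = numeric()))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  P <- params$population_size
  pop <- matrix(rep(init, each = P), nrow = P)
  flips <- matrix(stats::runif((P - 1L) * k) < params$mutation_prob,
                  nrow = P - 1L)
  pop[-1L, ] <- xor(pop[-1L, , drop = FALSE], flips)
  fit <- apply(pop, 1L, fitness, problem = problem)
  trace <- numeric(params$generations + 1L)
  trace[[1L]] <- max(fit)
  e <- params$elitism_count
  for (gen in seq_len(params$generations)) {
    r <- rank(fit, ties.method = "first")
    pr <- r / sum(r)
    elite <- order(fit, decreasing = TRUE)[seq_len(e)]
    n_child <- P - e
    children <- matrix(FALSE, n_child, k)
    ci <- 1L
    while (ci <= n_child) {
      par <- sample.int(P, 2L, replace = TRUE, prob = pr)
      p1 <- pop[par[[1L]], ]
      p2 <- pop[par[[2L]], ]
      if (stats::runif(1L) < params$crossover_prob) {
        mask <- stats::runif(k) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1
        c2 <- p2
      }
      children[ci, ] <- c1
      if (ci + 1L <= n_child) children[ci + 1L, ] <- c2
      ci <- ci + 2L
    }
    mut <- matrix(stats::runif(n_child * k) < params$mutation_prob,
                  nrow = n_child)
    children <- xor(children, mut)
    child_fit <- apply(children, 1L, fitness, problem = problem)
    pop <- rbind(pop[elite, , drop = FALSE], children)
    fit <- c(fit[elite], child_fit)
    trace[[gen + 1L]] <- max(fit)
  }
  best <- which.max(fit)
  list(bits = as.logical(pop[best, ]), fitness = fit[[best]], trace = trace)
}

#' Exhaustive E-step oracle for small subsets
#'
#' Enumerates all `2^k` chromosomes (k = number of mutable bits,
#' capped at 20) and returns the global minimum of the subset sum of
#' squared residuals; ties are broken by the lexicographically smallest
#' bitstring. The assignment search is NP-complete in general, so this
#' oracle is only feasible — and only intended — for test-sized
#' subsets.
#'
#' @param problem a [subset_problem()].
#' @return list with `bits` (optimal chromosome) and `ssr` (its
#'   subset sum of squared residuals).
#' @export
brute_force_min_ssr <- function(problem) {
  k <- nrow(problem$mut)
  if (k > 20L) {
    .stop_typed("isoformGO_model_error",
                "brute force limited to <= 20 mutable bits (got %d)", k)
  }
  if (k == 0L) {
    return(list(bits = logical(), ssr = .subset_ssr(problem$base, problem)))
  }
  best_bits <- NULL
  best_ssr <- Inf
  for (i in 0:(2^k - 1)) {
    bits <- rev(as.logical(intToBits(i))[seq_len(k)])  # MSB first = lex order
    v <- .subset_ssr(decode_bits(bits, problem), problem)
    if (v < best_ssr) {  # strict: first hit in lex order wins ties
      best_ssr <- v
      best_bits <- bits
    }
  }
  list(bits = best_bits, ssr = best_ssr)
}
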