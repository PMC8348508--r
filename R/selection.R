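#' Genetic-algorithm configuration
#'
#' Defaults: population 100, 300 generations, crossover probability 0.8,
#' per-gene mutation probability 0.05 with cardinality repair, elitism 2,
#' tournament size 2. Fitness is always the PRESS-based leave-one-out Q2 of
#' the OLS fit on the training rows.
#'
#' @param population population size (>= 2).
#' @param generations number of generations.
#' @param p_crossover crossover probability.
#' @param p_mutation per-gene mutation probability.
#' @param elitism number of elite chromosomes copied unchanged.
#' @param tournament tournament size for parent selection.
#' @param seed integer RNG seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population = 100, generations = 300,
                      p_crossover = 0.8, p_mutation = 0.05,
                      elitism = 2, tournament = 2, seed = 1) {
  stopifnot(population >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            elitism >= 0, elitism < population)
  structure(list(population = population, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = elitism, tournament = tournament, seed = seed,
                 fitness = "Q2_LOO"),
            class = "ga_config")
}

# Fast Q2_LOO + R2_tr for a column subset; -Inf fitness on singular designs.
.subset_fitness <- function(X, y, idx, sst) {
  Xi <- cbind(1, X[, idx, drop = FALSE])
  fit <- tryCatch({
    R <- chol(crossprod(Xi))
    beta <- backsolve(R, forwardsolve(t(R), crossprod(Xi, y)))
    e <- y - drop(Xi %*% beta)
    V <- Xi %*% chol2inv(R)
    h <- rowSums(V * Xi)
    press_r <- e / (1 - h)
    if (any(!is.finite(press_r))) return(NULL)
    c(q2 = 1 - sum(press_r^2) / sst, r2 = 1 - sum(e^2) / sst)
  }, error = function(e) NULL)
  if (is.null(fit)) c(q2 = -Inf, r2 = -Inf) else fit
}

#' Genetic-algorithm descriptor-subset search scored by Q2_LOO
#'
#' Evolves fixed-size descriptor subsets (set-encoded chromosomes with
#' cardinality repair) over the training rows. Fitness is the leave-one-out
#' Q2 of the OLS fit, evaluated through the PRESS identity; singular
#' candidate designs receive fitness `-Inf` and are never propagated as
#' errors. The best chromosome is carried over by elitism, so the best
#' fitness is non-decreasing across generations. Results are deterministic
#' given `cfg$seed`.
#'
#' @param X training descriptor matrix (columns = candidate pool).
#' @param y training response.
#' @param m model size (number of descriptors per subset).
#' @param cfg a [ga_config()].
#' @param top number of distinct best candidates to return.
#' @return data.frame ranked by fitness with columns `names`
#'   (comma-separated descriptor names), `q2_loo`, `r2_tr`; attribute
#'   `"history"` holds the best fitness per generation.
#' @export
ga_mlr_search <- function(X, y, m, cfg = ga_config(), top = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(m >= 1L, p >= m)
  if (m >= n / 5) stop("model size m too large for ", n,
                       " training rows (need m < n/5)")
  sst <- sum((y - mean(y))^2)
  pool_names <- colnames(X)
  if (is.null(pool_names)) pool_names <- paste0("x", seq_len(p))

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  evaluate <- function(idx) {
    idx <- sort(idx)
    key <- paste(idx, collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- .subset_fitness(X, y, idx, sst)
      cache[[key]] <- val
    }
    val
  }

  withr::with_seed(cfg$seed, {
    popl <- replicate(cfg$population, sort(sample.int(p, m)), simplify = FALSE)
    fits <- t(vapply(popl, evaluate, numeric(2)))
    history <- numeric(cfg$generations)

    for (gen in seq_len(cfg$generations)) {
      ord <- order(-fits[, 1L])
      popl <- popl[ord]; fits <- fits[ord, , drop = FALSE]
      history[gen] <- fits[1L, 1L]

      pick <- function() {
        cand <- sample.int(cfg$population, cfg$tournament, replace = TRUE)
        popl[[min(cand)]]   # population is fitness-sorted
      }
      offspring <- vector("list", cfg$population)
      n_elite <- min(cfg$elitism, cfg$population)
      if (n_elite > 0L) offspring[seq_len(n_elite)] <- popl[seq_len(n_elite)]
      for (i in seq.int(n_elite + 1L, cfg$population)) {
        p1 <- pick(); p2 <- pick()
        child <- if (runif(1) < cfg$p_crossover) {
          u <- union(p1, p2)
          if (length(u) > m) sort(sample(u, m)) else u
        } else p1
        mut <- runif(length(child)) < cfg$p_mutation
        outside <- setdiff(seq_len(p), child)
        if (any(mut) && length(outside) >= sum(mut)) {
          repl <- outside[sample.int(length(outside), sum(mut))]
          child <- sort(c(child[!mut], repl))
        }
        offspring[[i]] <- child
      }
      popl <- offspring
      fits <- t(vapply(popl, evaluate, numeric(2)))
    }

    # rank all distinct evaluated subsets
    keys <- ls(cache)
    scores <- t(vapply(keys, function(k) cache[[k]], numeric(2)))
    idx_list <- strsplit(keys, ",", fixed = TRUE)
    name_str <- vapply(idx_list, function(ii)
      paste(pool_names[as.integer(ii)], collapse = ","), character(1))
    ord <- order(-scores[, 1L], name_str)
    res <- data.frame(names = name_str[ord],
                      q2_loo = scores[ord, 1L],
                      r2_tr = scores[ord, 2L],
                      stringsAsFactors = FALSE)
    res <- head(res, top)
    attr(res, "history") <- history
    res
  })
}

#' Scan model sizes with the GA and collect the score curve
#'
#' Runs [ga_mlr_search()] for `m = 1..m_max` and returns the best
#' training-R2 / Q2_LOO per size (the input to [breaking_point()]).
#'
#' @param X,y training data.
#' @param m_max largest model size.
#' @param cfg a [ga_config()]; each size uses `cfg$seed + m`.
#' @return list with `scores` (data.frame `m`, `r2_tr`, `q2_loo`) and
#'   `best` (named list of the top candidate per size).
#' @export
model_size_scan <- function(X, y, m_max, cfg = ga_config()) {
  best <- list()
  rows <- vector("list", m_max)
  for (m in seq_len(m_max)) {
    cfg_m <- cfg
    cfg_m$seed <- cfg$seed + m
    res <- ga_mlr_search(X, y, m, cfg_m, top = 3L)
    best[[as.character(m)]] <- res
    rows[[m]] <- data.frame(m = m, r2_tr = res$r2_tr[1L],
                            q2_loo = res$q2_loo[1L])
  }
  list(scores = do.call(rbind, rows), best = best)
}

#' Choose the model size at the breaking point of the Q2 curve
#'
#' Returns the smallest size `m` whose successor adds less than `delta` to
#' Q2_LOO (`Q2(m+1) - Q2(m) < delta`); if every increment is at least
#' `delta` the largest scanned size is returned.
#'
#' @param scores data.frame with columns `m` and `q2_loo`, consecutive
#'   sizes starting anywhere, at least three rows.
#' @param delta minimum worthwhile gain in Q2_LOO (default 0.02).
#' @return the selected model size (integer).
#' @examples
#' breaking_point(data.frame(m = 1:5,
#'   q2_loo = c(0.40, 0.60, 0.75, 0.76, 0.765)))  # 3
#' @export
breaking_point <- function(scores, delta = 0.02) {
  stopifnot(all(c("m", "q2_loo") %in% names(scores)), nrow(scores) >= 3L)
  scores <- scores[order(scores$m), ]
  if (any(diff(scores$m) != 1L)) stop("model sizes must be consecutive")
  gain <- diff(scores$q2_loo)
  hit <- which(gain < delta)
  if (length(hit)) scores$m[hit[1L]] else scores$m[nrow(scores)]
}
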