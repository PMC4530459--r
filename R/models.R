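#' Substitution models
#'
#' Reversible continuous-time Markov models of sequence change with
#' discrete-gamma among-site rate variation.  Supported families:
#'
#' * `LG`, `WAG`: empirical amino-acid exchangeabilities and frequencies
#'   (read from the PAML-layout files shipped with the package).
#' * `GTR`: general time-reversible nucleotide model; six exchangeabilities
#'   (order AC, AG, AT, CG, CT, GT) and four frequencies.
#' * `CF2`: the two-state model of Cavender and Felsenstein for RY-recoded
#'   data; frequencies fixed at (1/2, 1/2).
#'
#' The rate matrix is `Q = S diag(pi)` with diagonals set so rows sum to 0,
#' normalized to one expected substitution per site at stationarity
#' (`-sum(pi_i Q_ii) = 1`).
#'
#' @param name model name, one of `"LG"`, `"WAG"`, `"GTR"`, `"CF2"`.
#' @param alpha gamma shape of among-site rate variation.
#' @param k number of discrete rate categories (default 4).
#' @param exch for GTR, the six exchangeabilities (default all 1).
#' @param freq for GTR, the four equilibrium frequencies (default uniform).
#' @return an object of class `paraconv_model` with elements `name`, `states`,
#'   `S` (symmetric exchangeability matrix), `pi`, `alpha`, `k`, `alphabet`
#'   and the cached spectral decomposition used to form transition matrices.
#' @export
build_model <- function(name = c("LG", "WAG", "GTR", "CF2"), alpha = 1,
                        k = 4L, exch = NULL, freq = NULL) {
  name <- match.arg(name)
  if (alpha <= 0) stop("gamma shape must be positive", call. = FALSE)
  if (name %in% c("LG", "WAG")) {
    dat <- read_paml_dat(system.file("extdata",
                                     paste0(tolower(name), ".dat"),
                                     package = "paraconv"))
    states <- aa_states()
    S <- dat$S
    pi <- dat$pi
    alphabet <- "AA"
  } else if (name == "GTR") {
    states <- c("A", "C", "G", "T")
    if (is.null(exch)) exch <- rep(1, 6)
    if (is.null(freq)) freq <- rep(0.25, 4)
    if (length(exch) != 6L) stop("GTR needs 6 exchangeabilities", call. = FALSE)
    if (length(freq) != 4L) stop("GTR needs 4 frequencies", call. = FALSE)
    S <- matrix(0, 4, 4, dimnames = list(states, states))
    S["A", "C"] <- S["C", "A"] <- exch[1]
    S["A", "G"] <- S["G", "A"] <- exch[2]
    S["A", "T"] <- S["T", "A"] <- exch[3]
    S["C", "G"] <- S["G", "C"] <- exch[4]
    S["C", "T"] <- S["T", "C"] <- exch[5]
    S["G", "T"] <- S["T", "G"] <- exch[6]
    pi <- freq
    alphabet <- "NT"
  } else {  # CF2
    states <- c("R", "Y")
    S <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(states, states))
    pi <- c(0.5, 0.5)
    alphabet <- "RY"
  }
  if (any(pi <= 0)) stop("non-positive equilibrium frequencies", call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- states
  model <- structure(list(name = name, states = states, S = S, pi = pi,
                          alpha = alpha, k = as.integer(k),
                          alphabet = alphabet),
                     class = "paraconv_model")
  model$eig <- model_eigen(model)
  model
}

#' @export
print.paraconv_model <- function(x, ...) {
  cat("<paraconv_model> ", x$name, " (", length(x$states),
      " states), gamma shape ", signif(x$alpha, 4), " with ", x$k,
      " categories\n", sep = "")
  invisible(x)
}

# amino-acid state order used throughout (PAML convention)
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# parse a PAML-layout model file: 19 lower-triangle rows, then frequencies
read_paml_dat <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l)
    scan(text = l, what = numeric(), quiet = TRUE))
  tri <- vals[1:19]
  freq <- vals[[20]]
  S <- matrix(0, 20, 20, dimnames = list(aa_states(), aa_states()))
  for (i in 2:20) S[i, 1:(i - 1)] <- S[1:(i - 1), i] <- tri[[i - 1]]
  list(S = S, pi = freq / sum(freq))
}

#' Normalized rate matrix of a model
#'
#' `Q = S diag(pi)`, diagonal set so rows sum to zero, scaled so the expected
#' rate at stationarity is one substitution per site.
#'
#' @param model a `paraconv_model`.
#' @return the rate matrix (states x states).
#' @export
rate_matrix <- function(model) {
  Q <- model$S %*% diag(model$pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(model$pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(model$states, model$states)
  Q
}

# symmetric spectral decomposition of Q: P(t) = U exp(diag(lambda) t) W
model_eigen <- function(model) {
  Q <- rate_matrix(model)
  sp <- sqrt(model$pi)
  A <- diag(sp) %*% Q %*% diag(1 / sp)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(U = diag(1 / sp) %*% e$vectors,
       W = t(e$vectors) %*% diag(sp),
       lambda = e$values)
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `k` equal-probability bins of a Gamma(shape = alpha,
#' rate = alpha) distribution, renormalized so their mean is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` rates, each with weight `1/k`.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("gamma shape must be positive", call. = FALSE)
  if (k < 1L) stop("need at least one rate category", call. = FALSE)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                     rate = alpha)
  # E[X ; X in bin] / P(bin) via the Gamma(alpha + 1) identity
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(cum)
  r / mean(r)
}

#' Transition probability matrix P(t)
#'
#' @param model a `paraconv_model`.
#' @param t branch length in expected substitutions per site (>= 0).
#' @param rate rate multiplier (e.g., a discrete-gamma category rate).
#' @return row-stochastic matrix `expm(Q t rate)`.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  e <- model$eig
  P <- e$U %*% (exp(e$lambda * t * rate) * e$W)
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

# encode alignment characters as 0-based state indices (-1 = gap/unknown)
encode_states <- function(aln, model) {
  m <- unclass(aln)
  idx <- match(m, model$states)
  if (model$alphabet == "NT") {
    u <- m == "U"
    idx[u] <- match("T", model$states)
  }
  idx[is.na(idx)] <- 0L
  out <- matrix(as.integer(idx - 1L), nrow(m), ncol(m))
  rownames(out) <- rownames(m)
  out
}

# model/alphabet compatibility check
check_model_alphabet <- function(aln, model) {
  if (attr(aln, "alphabet") != model$alphabet)
    stop("alphabet/model mismatch: alignment is ", attr(aln, "alphabet"),
         " but model ", model$name, " expects ", model$alphabet,
         call. = FALSE)
  invisible(TRUE)
}
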