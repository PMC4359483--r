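## Observation likelihoods and parent-child transition kernels.
##
## Each clone carries a real parameter theta_i per marker site; the chance of
## observing a 1 (methylated / mutated) at site i is sigmoid(theta_i). The
## parent-child kernel is a two-component Laplace mixture whose weights come
## from a two-state continuous-time Markov chain over the discretised states
## u (theta < eta) and m (theta >= eta), run for the branch length t.

.SIG_EPS <- 1e-15

#' Evolution model hyperparameters
#'
#' Bundles the hyperparameters of the marker evolution model: the Laplace
#' mixture mode location \code{mu} and scale \code{Lambda}, the state-call
#' threshold \code{eta}, the equilibrium frequencies \code{betaM} (methylated
#' or mutated) and \code{betaU}, and the rate scaling \code{rho}. For the
#' methylation model \code{rho} is fixed by \eqn{2\beta_u\beta_m\rho = 1}
#' (average methylation rate one); for the SNV model by
#' \eqn{\beta_m(1-\beta_m)\rho = 1}. The default \code{eta = 1} makes very
#' conservative methylation calls.
#'
#' @param kind \code{"methylation"} or \code{"snv"}.
#' @param betaM equilibrium frequency of the methylated/mutated state,
#'   strictly inside (0, 1).
#' @param mu Laplace mode location (> 0 separates the modes).
#' @param Lambda Laplace scale (> 0).
#' @param eta state-call threshold.
#' @return A list with class \code{"evolutionParams"}.
#' @examples
#' evolutionParams("methylation", betaM = 0.5)$rho  # 2
#' @export
evolutionParams <- function(kind = c("methylation", "snv"), betaM,
                            mu = 4, Lambda = 1, eta = 1) {
    kind <- match.arg(kind)
    if (betaM <= 0 || betaM >= 1)
        stop("betaM must lie strictly between 0 and 1 (degenerate equilibrium)")
    if (Lambda <= 0) stop("Lambda must be positive")
    betaU <- 1 - betaM
    rho <- if (kind == "methylation") 1 / (2 * betaU * betaM)
           else 1 / (betaM * (1 - betaM))
    structure(list(kind = kind, betaM = betaM, betaU = betaU, rho = rho,
                   mu = mu, Lambda = Lambda, eta = eta),
              class = "evolutionParams")
}

#' Laplace draws and log-density
#'
#' @param n number of draws.
#' @param location,scale Laplace location and scale; the density is
#'   \eqn{\exp(-|x-\mathrm{location}|/\mathrm{scale})/(2\,\mathrm{scale})}.
#' @return \code{rlaplace}: numeric draws; \code{dlaplaceLog}: log-density.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
    u <- stats::runif(n) - 0.5
    location - scale * sign(u) * log1p(-2 * abs(u))
}

#' @rdname rlaplace
#' @param x quantile(s).
#' @export
dlaplaceLog <- function(x, location = 0, scale = 1) {
    if (scale <= 0) stop("Laplace scale must be positive")
    -abs(x - location) / scale - log(2 * scale)
}

#' Per-observation log-likelihood under a clone
#'
#' Bernoulli log-likelihood of one binary marker row under a clone parameter
#' vector: \eqn{\sum_i x_i \log\sigma(\theta_i) + (1-x_i)\log(1 -
#' \sigma(\theta_i))}, with \eqn{\sigma} the logistic sigmoid. Missing sites
#' (NA in \code{x}) are ignored, which is the correct treatment when entries
#' are missing completely at random (e.g. allele dropout).
#'
#' @param x length-M vector with entries 0, 1 or NA.
#' @param theta length-M real parameter vector.
#' @return The log-likelihood (a scalar).
#' @examples
#' localLogLik(c(1, 0), c(0, 0))   # log(0.25)
#' @export
localLogLik <- function(x, theta) {
    if (length(x) != length(theta))
        stop("x and theta must have the same length")
    s <- pmin(pmax(stats::plogis(theta), .SIG_EPS), 1 - .SIG_EPS)
    keep <- !is.na(x)
    sum(x[keep] * log(s[keep]) + (1 - x[keep]) * log(1 - s[keep]))
}

#' Two-state rate matrix
#'
#' Builds the continuous-time Markov chain generator over the states (u, m).
#' Methylation: \eqn{A = \rho \,[\,-\beta_m, \beta_m; \beta_u, -\beta_u\,]}
#' with \eqn{\rho = 1/(2\beta_u\beta_m)} (both directions allowed: CpG sites
#' can methylate and demethylate). SNV: \eqn{A = \rho\,[\,-\beta_m, \beta_m;
#' 0, 0\,]} with \eqn{\rho = 1/(\beta_m(1-\beta_m))}, encoding irreversible
#' mutations. Rows sum to zero.
#'
#' @param kind \code{"methylation"} or \code{"snv"}.
#' @param betaM equilibrium methylated/mutated frequency in (0, 1).
#' @return 2x2 rate matrix with rows/columns ordered (u, m).
#' @examples
#' rateMatrix("methylation", 0.5)   # [[-1, 1], [1, -1]]
#' rateMatrix("snv", 0.5)           # [[-2, 2], [0, 0]]
#' @export
rateMatrix <- function(kind = c("methylation", "snv"), betaM) {
    kind <- match.arg(kind)
    if (betaM <= 0 || betaM >= 1)
        stop("degenerate equilibrium: betaM must lie strictly in (0, 1)")
    betaU <- 1 - betaM
    if (kind == "methylation") {
        rho <- 1 / (2 * betaU * betaM)
        A <- matrix(c(-betaM, betaU, betaM, -betaU), 2, 2) * rho
    } else {
        rho <- 1 / (betaM * (1 - betaM))
        A <- matrix(c(-betaM, 0, betaM, 0), 2, 2) * rho
    }
    dimnames(A) <- list(c("u", "m"), c("u", "m"))
    A
}

#' Transition matrix over a branch
#'
#' Matrix exponential \eqn{P(t) = \exp(At)} of a two-state generator,
#' computed in closed form: for \eqn{A = [\,-a, a; b, -b\,]} with total rate
#' \eqn{s = a + b}, \eqn{P(t) = \Pi + e^{-st}(I - \Pi)} where \eqn{\Pi} has
#' identical rows \eqn{(b/s, a/s)} (the stationary projector). Rows of the
#' result sum to one; \eqn{P(0) = I}. For the SNV generator the m-to-u entry
#' is exactly zero for every branch length.
#'
#' @param A 2x2 rate matrix as built by \code{\link{rateMatrix}}.
#' @param t branch length (nonnegative).
#' @return 2x2 row-stochastic transition matrix over (u, m).
#' @export
transitionMatrix <- function(A, t) {
    if (t < 0) stop("branch length must be nonnegative")
    a <- A[1, 2]; b <- A[2, 1]
    s <- a + b
    if (s == 0) {
        P <- diag(2)
    } else {
        Pi <- matrix(c(b, b, a, a) / s, 2, 2)
        P <- Pi + exp(-s * t) * (diag(2) - Pi)
    }
    dimnames(P) <- list(c("u", "m"), c("u", "m"))
    P
}

#' Laplace-mixture weight from the parent state
#'
#' Weight of the positive Laplace mode in the parent-child kernel at one
#' site: the probability of the child being methylated/mutated given the
#' parent's discretised state, read from the branch transition matrix. A
#' parent with \eqn{\theta \ge \eta} is in state m and contributes
#' \eqn{P_{m\to m}}; otherwise \eqn{P_{u\to m}}.
#'
#' @param thetaParent parent parameter value(s) at the site(s).
#' @param P 2x2 transition matrix from \code{\link{transitionMatrix}}.
#' @param eta state-call threshold.
#' @return Mixture weight(s) in [0, 1].
#' @export
mixtureWeight <- function(thetaParent, P, eta = 1) {
    P[1L, 2L] + (thetaParent >= eta) * (P[2L, 2L] - P[1L, 2L])
}

#' Discretised marker state of a clone parameter
#'
#' @param theta parameter value(s).
#' @param eta threshold; state is \code{"m"} iff \code{theta >= eta}.
#' @return Character vector of states \code{"u"}/\code{"m"}.
#' @export
callState <- function(theta, eta = 1) {
    ifelse(theta >= eta, "m", "u")
}

#' Parent-to-child transition log-density
#'
#' Log-density of a child clone parameter vector given its parent, under the
#' two-component Laplace mixture whose site-wise weights come from the
#' branch transition matrix: \eqn{\sum_i \log[ w_i\,\mathrm{Laplace}
#' (\theta_i; \mu, \Lambda) + (1-w_i)\,\mathrm{Laplace}(\theta_i; -\mu,
#' \Lambda)]}.
#'
#' @param thetaChild,thetaParent length-M parameter vectors.
#' @param t branch length (> 0).
#' @param params an \code{\link{evolutionParams}}.
#' @return The log-density (a scalar).
#' @export
transitionLogPdf <- function(thetaChild, thetaParent, t, params) {
    if (length(thetaChild) != length(thetaParent))
        stop("child and parent parameter vectors must have the same length")
    p <- .transProbs(params, t)
    w <- p[1L] + (thetaParent >= params$eta) * (p[2L] - p[1L])
    sum(.mixLaplaceLog(thetaChild, w, params$mu, params$Lambda))
}

## closed-form c(P_um, P_mm) of the two-state chain, equal to the matrix
## exponential entries (see transitionMatrix)
.transProbs <- function(params, t) {
    if (params$kind == "methylation") {
        e <- exp(-params$rho * t)
        c(params$betaM * (1 - e), params$betaM + (1 - params$betaM) * e)
    } else {
        c(1 - exp(-params$rho * params$betaM * t), 1)
    }
}

## site-wise log of w*La(+mu) + (1-w)*La(-mu), stable for w in {0,1}
.mixLaplaceLog <- function(x, w, mu, Lambda) {
    lp <- dlaplaceLog(x, mu, Lambda)
    lm <- dlaplaceLog(x, -mu, Lambda)
    a <- log(w) + lp       # -Inf when w = 0
    b <- log1p(-w) + lm    # -Inf when w = 1
    hi <- pmax(a, b)
    lo <- pmin(a, b)
    out <- hi + log1p(exp(lo - hi))
    out[is.infinite(hi)] <- -Inf
    ifelse(lo == -Inf, hi, out)
}

#' Root clone log-prior
#'
#' Independent Laplace priors centred at \eqn{-\mu} for every site of the
#' root parameter vector, favouring a fully unmethylated (wild-type) root
#' clone.
#'
#' @param thetaRoot root parameter vector.
#' @param mu,Lambda Laplace mode location and scale.
#' @return The log-prior (a scalar).
#' @export
rootLogPrior <- function(thetaRoot, mu, Lambda) {
    sum(dlaplaceLog(thetaRoot, -mu, Lambda))
}

## draw a child's theta from the transition kernel given the parent;
## closed-form two-state transition probabilities, no matrix construction
.drawChildTheta <- function(thetaParent, t, params) {
    M <- length(thetaParent)
    if (!M) return(numeric(0))
    betaM <- params$betaM
    if (params$kind == "methylation") {
        e <- exp(-params$rho * t)
        Pum <- betaM * (1 - e)
        Pmm <- betaM + (1 - betaM) * e
    } else {
        e <- exp(-params$rho * betaM * t)
        Pum <- 1 - e
        Pmm <- 1
    }
    w <- ifelse(thetaParent >= params$eta, Pmm, Pum)
    pos <- stats::runif(M) < w
    rlaplace(M, params$mu * (2 * pos - 1), params$Lambda)
}
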