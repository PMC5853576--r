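#' @importFrom stats rnbinom rpois rlnorm rnorm runif setNames
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. seed = NULL runs in the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Positional-degradation retention factor
#'
#' Mean fraction of a transcript's signal retained when positional survival
#' decays as \eqn{e^{-k t}} with fractional distance \eqn{t} from the 3' end:
#' \eqn{R(k) = (1 - e^{-k})/k}, with the limit \eqn{R(0) = 1}. Here
#' \eqn{k = d s_g} is the product of sample degradation severity and
#' gene-specific sensitivity.
#'
#' @param k Nonnegative numeric vector.
#' @return Retention factors in (0, 1].
#' @examples
#' retentionFactor(c(0, 1, 4))
#' @export
retentionFactor <- function(k) {
    stopifnot(all(k >= 0))
    r <- ifelse(k < 1e-8, 1 - k / 2, (1 - exp(-k)) / k)
    r
}

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param noise_sigma Lognormal sigma for enzyme/metabolite abundance noise.
#' @param seed Integer seed; every simulated output is a deterministic
#'   function of it.
#' @param marker_ids Character pair `c(M-marker, BS-marker)` of gene ids used
#'   as pure-tissue transcript markers.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_genes = 2000, dispersion = 0.05, noise_sigma = 0.1,
                      seed = 1, marker_ids = c("PEPC", "NADPME")) {
    stopifnot(n_genes >= 1, dispersion >= 0, noise_sigma >= 0,
              length(marker_ids) == 2)
    structure(list(n_genes = as.integer(n_genes), dispersion = dispersion,
                   noise_sigma = noise_sigma, seed = as.integer(seed),
                   marker_ids = marker_ids),
              class = "SimConfig")
}

#' Simulate gene models
#'
#' Draws per-gene length, pure-tissue expression, and degradation
#' sensitivity. By default there is no true differential expression between
#' BS and M beyond the two marker genes (PEPC-like, purely mesophyll; and
#' NADP-ME-like, purely bundle sheath): every other gene has
#' `mu_bs == mu_m`. Degradation sensitivity \eqn{s_g} is a three-part
#' mixture emulating the observation that transcript degradation is highly
#' gene specific: a fraction of genes is insensitive (\eqn{s_g = 0}), most of
#' the remainder mildly sensitive, and a `frac_sensitive` minority strongly
#' sensitive.
#'
#' @param config A [simConfig()] object.
#' @param frac_zero_sens,frac_sensitive Fractions of genes with zero and with
#'   strong degradation sensitivity (the remainder is mildly sensitive).
#' @param sens_range,mild_range Ranges (uniform) for the strong and mild
#'   sensitivity classes.
#' @param de_frac Fraction of non-marker genes given true BS/M differential
#'   expression (default 0: mixtures contain no biological signal beyond the
#'   markers).
#' @param de_log2fc Standard deviation of the normal distribution the true
#'   log2 fold changes of DE genes are drawn from (most true effects are
#'   small, a minority large).
#' @return data.frame with columns `gene_id`, `length`, `mu_bs`, `mu_m`,
#'   `deg_sens`.
#' @export
simulateGeneModels <- function(config = simConfig(),
                               frac_zero_sens = 0.6, frac_sensitive = 0.1,
                               sens_range = c(1.5, 3), mild_range = c(0, 0.3),
                               de_frac = 0, de_log2fc = 1) {
    n <- config$n_genes
    stopifnot(n >= 3, frac_zero_sens + frac_sensitive <= 1)
    withSeed(config$seed, {
        len <- as.integer(pmin(pmax(round(rlnorm(n, log(1500), 0.45)), 300L), 5000L))
        mu <- rlnorm(n, log(100), 1)
        n_zero <- round(n * frac_zero_sens)
        n_sens <- round(n * frac_sensitive)
        n_mild <- n - n_zero - n_sens
        s <- c(rep(0, n_zero),
               runif(n_mild, mild_range[1], mild_range[2]),
               runif(n_sens, sens_range[1], sens_range[2]))
        s <- sample(s)
        mu_bs <- mu_m <- mu
        if (de_frac > 0) {
            idx <- sample(seq_len(n), round(n * de_frac))
            lfc <- rnorm(length(idx), 0, de_log2fc)
            mu_bs[idx] <- mu[idx] * 2^(lfc / 2)
            mu_m[idx] <- mu[idx] * 2^(-lfc / 2)
        }
        genes <- data.frame(
            gene_id = sprintf("gene%04d", seq_len(n)),
            length = len, mu_bs = mu_bs, mu_m = mu_m, deg_sens = s,
            stringsAsFactors = FALSE)
        ## the two transcript markers: pure M and pure BS, well expressed,
        ## degradation-insensitive so marker signal tracks tissue amount
        genes$gene_id[1:2] <- config$marker_ids
        genes$mu_m[1] <- 500; genes$mu_bs[1] <- 0
        genes$mu_bs[2] <- 500; genes$mu_m[2] <- 0
        genes$deg_sens[1:2] <- 0
        genes
    })
}

#' Sample sheets for the pseudo-study templates
#'
#' Templates mirror the three separation regimes compared in the
#' cross-study analysis: `"mech"` (mechanical/enzymatic separation: high
#' purity, low BS degradation but high M degradation), `"lmd"` (laser
#' micro-dissection: high purity, strong but equal degradation in both
#' tissues), `"filtration"` (serial filtration over liquid nitrogen: three
#' enrichment fractions of modest purity, low equal degradation), and
#' `"unseparated"` (whole-tissue controls).
#'
#' @param template One of `"mech"`, `"lmd"`, `"filtration"`, `"unseparated"`.
#' @param study_id Study identifier put in the sheet.
#' @param slice Developmental slice label (integer, 1 = tip).
#' @param replicates Replicates per fraction/tissue.
#' @param lib_size Library size per sample.
#' @param d_bs,d_m,d Degradation severities; defaults are the template
#'   values (mech: d_bs 0.3 / d_m 2; lmd: 3 both; filtration/unseparated:
#'   0.2). For `"filtration"` and `"unseparated"` the single `d` applies to
#'   all samples.
#' @param purities For `"filtration"`: BS purities of the BS-e/I-e/M-e
#'   fractions.
#' @return data.frame of sample specifications (see [MixtureExperiment()]).
#' @export
studyTemplate <- function(template = c("mech", "lmd", "filtration",
                                       "unseparated"),
                          study_id = template, slice = 2L, replicates = 4L,
                          lib_size = 2e6, d_bs = NULL, d_m = NULL, d = NULL,
                          purities = c(BS_e = 0.7, I_e = 0.5, M_e = 0.3)) {
    template <- match.arg(template)
    rep_ids <- seq_len(replicates)
    mk <- function(label, purity, dsev) {
        data.frame(
            sample_id = sprintf("%s_s%d_%s_r%d", study_id, slice, label, rep_ids),
            study_id = study_id, slice = as.integer(slice), label = label,
            purity_bs = purity, deg_severity = dsev, lib_size = lib_size,
            stringsAsFactors = FALSE)
    }
    switch(template,
        mech = rbind(mk("BS", 0.95, if (is.null(d_bs)) 0.3 else d_bs),
                     mk("M", 0.05, if (is.null(d_m)) 2 else d_m)),
        lmd = rbind(mk("BS", 0.98, if (is.null(d_bs)) 3 else d_bs),
                    mk("M", 0.02, if (is.null(d_m)) 3 else d_m)),
        filtration = {
            dd <- if (is.null(d)) 0.2 else d
            rbind(mk("BS_e", purities[["BS_e"]], dd),
                  mk("I_e", purities[["I_e"]], dd),
                  mk("M_e", purities[["M_e"]], dd))
        },
        unseparated = mk("unseparated", 0.5, if (is.null(d)) 0.2 else d))
}

#' Simulate a count matrix from the mixture-plus-degradation model
#'
#' Expected signal for gene g in sample s is
#' \eqn{e_{gs} = \pi_s \mu_{BS,g} + (1-\pi_s)\mu_{M,g}}, attenuated by the
#' retention factor \eqn{R_{gs} = R(d_s s_g)} (see [retentionFactor()]),
#' scaled to the sample's library size, and observed with negative binomial
#' noise (`var = mu + phi mu^2`; Poisson when `phi = 0`).
#'
#' @param genes Gene models ([simulateGeneModels()]).
#' @param samples Sample sheet ([studyTemplate()] or hand-built).
#' @param config A [simConfig()]; `dispersion` and `seed` are used.
#' @return A [MixtureExperiment-class] with assays `counts`, `expected`
#'   (expected counts) and `retention`.
#' @export
simulateCounts <- function(genes, samples, config = simConfig()) {
    if (nrow(genes) == 0) stop("empty gene list")
    stopifnot(all(genes$length >= 1), all(genes$deg_sens >= 0),
              all(samples$purity_bs >= 0 & samples$purity_bs <= 1),
              all(samples$deg_severity >= 0), all(samples$lib_size > 0),
              config$dispersion >= 0)
    G <- nrow(genes); S <- nrow(samples)
    e <- outer(genes$mu_bs, samples$purity_bs) +
         outer(genes$mu_m, 1 - samples$purity_bs)
    k <- outer(genes$deg_sens, samples$deg_severity)
    R <- matrix(retentionFactor(as.vector(k)), G, S)
    w <- e * R
    mu <- sweep(w, 2, colSums(w), "/")
    mu <- sweep(mu, 2, samples$lib_size, "*")
    phi <- config$dispersion
    counts <- withSeed(config$seed, {
        if (phi > 0) {
            matrix(rnbinom(G * S, mu = as.vector(mu), size = 1 / phi), G, S)
        } else {
            matrix(rpois(G * S, as.vector(mu)), G, S)
        }
    })
    MixtureExperiment(counts, genes, samples, expected = mu, retention = R)
}

#' Simulate a per-transcript coverage profile
#'
#' Coverage at 0-based position i (5' to 3') is proportional to
#' \eqn{e^{-d s_g t(i)}} with \eqn{t(i) = (L-1-i)/(L-1)} the fractional
#' distance from the 3' end: degradation removes 5' signal first, so
#' coverage rises towards the 3' end. `mode = "expected"` returns the
#' deterministic profile; `mode = "poisson"` adds Poisson counting noise.
#'
#' @param length Transcript length in nt (>= 1).
#' @param d Sample degradation severity.
#' @param deg_sens Gene degradation sensitivity \eqn{s_g}.
#' @param depth Expected coverage depth at the (undegraded) 3' end.
#' @param mode `"expected"` or `"poisson"`.
#' @param seed Optional seed for Poisson mode.
#' @return Numeric vector of length `length`, 5' to 3'.
#' @export
simulateCoverage <- function(length, d, deg_sens, depth = 50,
                             mode = c("expected", "poisson"), seed = NULL) {
    mode <- match.arg(mode)
    length <- as.integer(length)
    if (length < 1) stop("transcript length must be >= 1")
    stopifnot(d >= 0, deg_sens >= 0, depth > 0)
    t_frac <- if (length == 1) 0 else (length - 1 - seq_len(length) + 1) / (length - 1)
    cov <- depth * exp(-d * deg_sens * t_frac)
    if (mode == "poisson") cov <- withSeed(seed, rpois(length, cov))
    cov
}

#' Simulate an enzyme/metabolite abundance table
#'
#' Each analyte a has a true fraction-in-pure-BS `alpha`; its expected
#' abundance in a fraction with BS purity \eqn{\pi_f} is
#' \eqn{\pi_f (2\alpha\,scale) + (1-\pi_f)(2(1-\alpha)\,scale)}, observed
#' with multiplicative lognormal noise. The table always contains the two
#' marker analytes: the M marker (`alpha = 0`, e.g. PEPC activity) and the
#' BS marker (`alpha = 1`, e.g. NADP-ME activity).
#'
#' @param analytes data.frame with columns `analyte_id`, `alpha` (in
#'   `[0, 1]`) and `scale` (positive); markers are appended if absent.
#' @param purities Named BS purities of the enrichment fractions
#'   (2-5 fractions).
#' @param replicates Replicates per fraction (>= 1).
#' @param config A [simConfig()]; `noise_sigma`, `seed` and `marker_ids`
#'   are used.
#' @param slice Developmental slice label.
#' @return data.frame with columns `analyte_id`, `slice`, `fraction`,
#'   `replicate`, `value`.
#' @export
simulateActivityTable <- function(analytes,
                                  purities = c(BS_e = 0.7, I_e = 0.5, M_e = 0.3),
                                  replicates = 4L, config = simConfig(),
                                  slice = 2L) {
    stopifnot(length(purities) >= 2, length(purities) <= 5, replicates >= 1)
    if (any(analytes$alpha < 0 | analytes$alpha > 1))
        stop("alpha must lie in [0, 1]")
    stopifnot(all(analytes$scale > 0))
    markers <- data.frame(
        analyte_id = config$marker_ids, alpha = c(0, 1), scale = c(1, 1),
        stringsAsFactors = FALSE)
    add <- !markers$analyte_id %in% analytes$analyte_id
    analytes <- rbind(analytes[, c("analyte_id", "alpha", "scale")],
                      markers[add, ])
    grid <- expand.grid(replicate = seq_len(replicates),
                        fraction = names(purities),
                        analyte_id = analytes$analyte_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$slice <- as.integer(slice)
    a <- analytes[match(grid$analyte_id, analytes$analyte_id), ]
    pi_f <- purities[grid$fraction]
    mu <- pi_f * (2 * a$alpha * a$scale) + (1 - pi_f) * (2 * (1 - a$alpha) * a$scale)
    noise <- withSeed(config$seed,
                      rlnorm(nrow(grid), 0, config$noise_sigma))
    grid$value <- as.numeric(mu * noise)
    grid[, c("analyte_id", "slice", "fraction", "replicate", "value")]
}
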