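#' Hansen solubility parameter triple
#'
#' Constructs the three-component Hansen solubility parameter (HSP) vector:
#' dispersion (`delta_d`), polar (`delta_p`) and hydrogen-bonding (`delta_h`)
#' contributions to the cohesive energy density, each in MPa^0.5.
#'
#' @param delta_d Dispersion component, MPa^0.5. Non-negative.
#' @param delta_p Polar component, MPa^0.5. Non-negative.
#' @param delta_h Hydrogen-bonding component, MPa^0.5. Non-negative.
#'
#' @return An object of class `"hsp"`: a named numeric vector of length 3.
#' @examples
#' hsp(17.29, 8.2, 11.2) # cefdinir
#' @export
hsp <- function(delta_d, delta_p, delta_h) {
  x <- c(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h)
  if (length(x) != 3L || !is.numeric(x) || anyNA(x)) {
    stop("hsp() requires three finite numeric components", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("Hansen components must be non-negative (got ",
         paste(signif(x, 4), collapse = ", "), ")", call. = FALSE)
  }
  structure(as.numeric(x), names = names(x), class = "hsp")
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf("<hsp> delta_d = %.2f, delta_p = %.2f, delta_h = %.2f MPa^0.5\n",
              x[["delta_d"]], x[["delta_p"]], x[["delta_h"]]))
  invisible(x)
}

as_hsp <- function(x) {
  if (inherits(x, "hsp")) return(x)
  if (inherits(x, "substance")) return(x$hsp)
  if (is.numeric(x) && length(x) == 3L) return(hsp(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as Hansen components", call. = FALSE)
}

#' Total (Hildebrand-equivalent) solubility parameter
#'
#' The magnitude of the HSP vector, `delta_t = sqrt(delta_d^2 + delta_p^2 +
#' delta_h^2)`, in MPa^0.5.
#'
#' @param x An [hsp()] object, a [substance()], or a numeric vector of the
#'   three components.
#' @return Total solubility parameter in MPa^0.5.
#' @examples
#' total_parameter(hsp(3, 0, 4)) # 5
#' @export
total_parameter <- function(x) {
  h <- as_hsp(x)
  sqrt(sum(h^2))
}

#' Hansen interaction radius between two substances
#'
#' Distance in Hansen space, `Ra = sqrt(4 (dd1 - dd2)^2 + (dp1 - dp2)^2 +
#' (dh1 - dh2)^2)`, in MPa^0.5. The factor 4 on the dispersion term is the
#' standard Hansen weighting. Smaller Ra means stronger predicted affinity.
#'
#' @param a,b [hsp()] objects (or [substance()]s / numeric triples).
#' @return Ra in MPa^0.5; symmetric in its arguments, zero iff `a == b`.
#' @examples
#' interaction_radius(hsp(17.29, 8.2, 11.2), hsp(18.5, 8.0, 12.0))
#' @export
interaction_radius <- function(a, b) {
  ha <- as_hsp(a)
  hb <- as_hsp(b)
  d <- ha - hb
  sqrt(4 * d[["delta_d"]]^2 + d[["delta_p"]]^2 + d[["delta_h"]]^2)
}

#' Miscibility thresholds
#'
#' Classification cut-offs used throughout the screen. Pairs with Ra below
#' `ra_miscible` are taken as miscible, above `ra_immiscible` as immiscible,
#' and in between as borderline; Flory-Huggins chi below `chi_miscible`
#' indicates thermodynamic miscibility. Comparisons are strict at both Ra
#' bounds and at the chi bound (Ra exactly at a bound is borderline; chi
#' exactly at the bound is not miscible).
#'
#' @param ra_miscible Upper Ra bound for miscibility, MPa^0.5 (default 7).
#'   Some practitioners prefer a stricter bound of 5 MPa^0.5; pass
#'   `ra_miscible = 5` for that convention.
#' @param ra_immiscible Lower Ra bound for immiscibility, MPa^0.5 (default 10).
#' @param chi_miscible Chi bound for miscibility, dimensionless (default 0.5).
#' @return An object of class `"miscibility_thresholds"`.
#' @export
miscibility_thresholds <- function(ra_miscible = 7, ra_immiscible = 10,
                                   chi_miscible = 0.5) {
  stopifnot(is.numeric(ra_miscible), is.numeric(ra_immiscible),
            is.numeric(chi_miscible))
  if (ra_miscible >= ra_immiscible) {
    stop("ra_miscible must be strictly below ra_immiscible", call. = FALSE)
  }
  if (chi_miscible <= 0) stop("chi_miscible must be positive", call. = FALSE)
  structure(list(ra_miscible = ra_miscible, ra_immiscible = ra_immiscible,
                 chi_miscible = chi_miscible),
            class = "miscibility_thresholds")
}

#' Classify a pair by its Hansen interaction radius
#'
#' @param ra Interaction radius, MPa^0.5 (non-negative).
#' @param thresholds A [miscibility_thresholds()] object.
#' @return One of `"miscible"`, `"borderline"`, `"immiscible"`.
#' @examples
#' classify_by_ra(2.56) # miscible
#' classify_by_ra(8.5)  # borderline
#' @export
classify_by_ra <- function(ra, thresholds = miscibility_thresholds()) {
  stopifnot(inherits(thresholds, "miscibility_thresholds"))
  if (!is.numeric(ra) || anyNA(ra) || any(ra < 0)) {
    stop("ra must be a non-negative number", call. = FALSE)
  }
  ifelse(ra < thresholds$ra_miscible, "miscible",
         ifelse(ra > thresholds$ra_immiscible, "immiscible", "borderline"))
}
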