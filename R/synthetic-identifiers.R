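#' NHS number check-digit validation
#'
#' Validates a 10-digit NHS number under the national modulus-11 scheme:
#' the first nine digits are weighted 10 down to 2, summed, and the check
#' digit is `11 - (sum mod 11)`, with 11 mapped to 0 and 10 meaning the
#' number is never issued.
#'
#' @param nhs_number Character vector of candidate numbers.
#' @return Logical vector, `TRUE` where the number is 10 digits with a valid
#'   check digit.
#' @export
validate_nhs_number <- function(nhs_number) {
  x <- as.character(nhs_number)
  ok_form <- !is.na(x) & grepl("^\\d{10}$", x)
  out <- rep(FALSE, length(x))
  if (!any(ok_form)) return(out)
  xs <- x[ok_form]
  digs <- matrix(as.integer(unlist(strsplit(xs, ""), use.names = FALSE)),
                 ncol = 10, byrow = TRUE)
  check <- nhs_check_digit(digs[, 1:9, drop = FALSE])
  out[ok_form] <- !is.na(check) & check == digs[, 10]
  out
}

# check digit from a matrix of the 9 leading digits; NA where the scheme
# yields 10 (no such number is ever issued)
nhs_check_digit <- function(d9) {
  w <- 10:2
  s <- as.vector(d9 %*% w)
  chk <- 11L - (s %% 11L)
  chk[chk == 11L] <- 0L
  chk[chk == 10L] <- NA_integer_
  chk
}

#' Generate synthetic patient identifier sets
#'
#' Produces `n` fictitious women, each with a distinct check-digit-valid NHS
#' number, a site-scoped hospital number, a date of birth drawn uniformly
#' from `dob_range`, and a synthetic UK-format postcode.
#'
#' @param n Number of identifier sets (may be 0).
#' @param dob_range Length-2 Date vector `c(start, end)`, inclusive.
#' @param seed Integer seed; the output is deterministic given `(n, dob_range,
#'   seed)`.
#' @param site_code Prefix used for hospital numbers.
#' @return A tibble with columns `nhs_number`, `hospital_number`, `dob`,
#'   `postcode`.
#' @export
generate_identifiers <- function(n, dob_range, seed = 1L, site_code = "S01") {
  dob_range <- as.Date(dob_range)
  if (length(dob_range) != 2L || anyNA(dob_range) || dob_range[1] > dob_range[2])
    config_error("dob_range must be two ordered dates")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    config_error("n must be a non-negative count")
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble(nhs_number = character(0), hospital_number = character(0),
                  dob = as.Date(character(0)), postcode = character(0)))
  }
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    nhs <- generate_nhs_numbers(n)
    days <- as.integer(dob_range[2] - dob_range[1])
    dob <- dob_range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
    hosp <- sprintf("%s-H%07d", site_code, sample.int(9999999L, n))
    postcode <- random_postcodes(n)
    tibble(nhs_number = nhs, hospital_number = hosp, dob = dob,
           postcode = postcode)
  })
}

# n distinct valid NHS numbers; draws 9-digit bodies without replacement and
# appends the modulus-11 check digit, rejecting check-10 bodies
generate_nhs_numbers <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    body <- sample.int(1000000000L, size = ceiling(need * 1.15) + 10L) - 1L
    bs <- sprintf("%09d", body)
    digs <- matrix(as.integer(unlist(strsplit(bs, ""), use.names = FALSE)),
                   ncol = 9, byrow = TRUE)
    chk <- nhs_check_digit(digs)
    keep <- !is.na(chk)
    out <- unique(c(out, paste0(bs[keep], chk[keep])))
  }
  out[seq_len(n)]
}

# plausible-looking UK postcodes (synthetic; not real geographies)
random_postcodes <- function(n) {
  area <- c("AB", "BR", "CM", "DL", "EX", "FY", "GU", "HA", "IG", "KT",
            "LS", "ME", "NW", "OX", "PE", "RG", "SE", "TN", "UB", "WD")
  sprintf("%s%d %d%s%s",
          sample(area, n, replace = TRUE),
          sample.int(20L, n, replace = TRUE),
          sample.int(9L, n, replace = TRUE),
          sample(LETTERS[1:20], n, replace = TRUE),
          sample(LETTERS[1:20], n, replace = TRUE))
}
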