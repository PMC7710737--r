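#' IP-versus-input enrichment in predefined transcript domains
#'
#' For each named domain the enrichment is the ratio of
#' within-transcript read fractions,
#' `((ip_domain + pc) / (ip_total + pc)) / ((input_domain + pc) / (input_total + pc))`.
#' Normalizing by each library's total reads on the transcript makes the
#' statistic invariant to sequencing depth and to overall transcript
#' expression differences between alleles or conditions.
#'
#' All alleles' reads are mapped to the same wild-type mature transcript, so
#' reads from a relocated repeat insertion multi-map back to the original
#' repeat locus; `mask` removes such an interval from both tracks (and the
#' totals) before quantification.
#'
#' @param ipCoverage,inputCoverage equal-length per-nt read coverage vectors.
#' @param domains named [IRanges::IRanges] of domain intervals, or a
#'   `data.frame` with `name`, `start`, `end` (1-based closed).
#' @param pseudocount added to domain and total sums (default 1).
#' @param mask optional [IRanges::IRanges] zeroed out of both tracks first.
#' @return `data.frame` with `domain`, `start`, `end`, `ip_fraction`,
#'   `input_fraction`, `enrichment`.
#' @examples
#' ip <- rep(1, 1000); ip[101:200] <- 9
#' inp <- rep(1, 1000)
#' domainEnrichment(ip, inp, IRanges::IRanges(101, 200, names = "D1"))
#' @export
domainEnrichment <- function(ipCoverage, inputCoverage, domains,
                             pseudocount = 1, mask = NULL) {
  if (length(ipCoverage) != length(inputCoverage))
    stop("IP and input coverage vectors must have equal length")
  if (is.data.frame(domains)) {
    d <- IRanges(domains$start, domains$end)
    names(d) <- domains$name
    domains <- d
  }
  L <- length(ipCoverage)
  if (any(start(domains) < 1L) || any(end(domains) > L))
    stop("domain outside coverage bounds [1, ", L, "]")
  if (!is.null(mask)) {
    for (i in seq_along(mask)) {
      idx <- start(mask)[i]:min(end(mask)[i], L)
      ipCoverage[idx] <- 0
      inputCoverage[idx] <- 0
    }
  }
  ipTotal <- sum(ipCoverage); inTotal <- sum(inputCoverage)
  if (ipTotal == 0 || inTotal == 0)
    stop("zero total coverage in IP or input track")
  cumIp <- cumsum(ipCoverage); cumIn <- cumsum(inputCoverage)
  sumIn <- function(cs, s, e) cs[e] - if (s > 1L) cs[s - 1L] else 0
  n <- length(domains)
  ipd <- ind <- numeric(n)
  for (i in seq_len(n)) {
    ipd[i] <- sumIn(cumIp, start(domains)[i], end(domains)[i])
    ind[i] <- sumIn(cumIn, start(domains)[i], end(domains)[i])
  }
  ipf <- (ipd + pseudocount) / (ipTotal + pseudocount)
  inf <- (ind + pseudocount) / (inTotal + pseudocount)
  data.frame(domain = if (!is.null(names(domains))) names(domains)
                      else as.character(seq_len(n)),
             start = start(domains), end = end(domains),
             ip_fraction = ipf, input_fraction = inf,
             enrichment = ipf / inf)
}

#' Per-domain log2 enrichment ratios relative to a reference allele
#'
#' Expresses each allele's domain enrichment relative to a reference allele
#' (typically wild type): `log2(enrichment_allele / enrichment_reference)`.
#' The reference's own ratios are identically 0. Every allele must carry the
#' same domain set.
#'
#' @param quants `data.frame` concatenating [domainEnrichment()] outputs
#'   with an added `allele` column.
#' @param reference the reference allele name (must be present).
#' @return `quants` with an added `log2_ratio_vs_reference` column.
#' @export
relativeToReference <- function(quants, reference = "WT") {
  if (!reference %in% quants$allele)
    stop("reference allele \"", reference, "\" not present")
  refq <- quants[quants$allele == reference, ]
  domains <- sort(unique(quants$domain))
  for (al in unique(quants$allele)) {
    if (!setequal(quants$domain[quants$allele == al], domains))
      stop("allele \"", al, "\" is missing domains present elsewhere")
  }
  if (anyDuplicated(refq$domain))
    stop("duplicated domain in reference allele")
  refEnr <- stats::setNames(refq$enrichment, refq$domain)
  quants$log2_ratio_vs_reference <-
    log2(quants$enrichment / refEnr[quants$domain])
  quants$log2_ratio_vs_reference[quants$allele == reference] <- 0
  quants
}

#' Write per-allele domain quantifications as long-format TSV
#'
#' @param quants output of [relativeToReference()].
#' @param file output path.
#' @export
writeDomainQuant <- function(quants, file) {
  cols <- intersect(c("allele", "domain", "start", "end", "ip_fraction",
                      "input_fraction", "enrichment",
                      "log2_ratio_vs_reference"), names(quants))
  utils::write.table(quants[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
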