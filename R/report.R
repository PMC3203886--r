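# Rendering of result objects as text, TSV or JSON reports.

fmt6 <- function(x) signif(x, 6)

report_list <- function(result) UseMethod("report_list")

#' @export
report_list.mt_lr <- function(result) {
  list(type = "lr", label_num = result$label_num,
       label_den = result$label_den,
       likelihood_num = fmt6(result$likelihood_num),
       likelihood_den = fmt6(result$likelihood_den),
       lr = fmt6(result$lr),
       log10_lr = if (result$lr > 0) fmt6(log10(result$lr)) else -Inf,
       detail = result$detail)
}

#' @export
report_list.mt_search <- function(result) {
  list(type = "deconvolution", status = result$status, m = result$m,
       n_solutions = length(result$solutions),
       solutions = lapply(result$solutions, function(s)
         unname(vapply(s, profile_key, character(1)))))
}

#' @export
report_list.mixture_fit <- function(result) {
  list(type = "mixture_fit",
       pair = c(profile_key(result$model$pair[[1]]),
                profile_key(result$model$pair[[2]])),
       beta_hat = fmt6(result$beta_hat), se = fmt6(result$se),
       r_squared = fmt6(result$r_squared),
       p_beta0 = fmt6(result$p_value_beta0),
       p_beta1 = fmt6(result$p_value_beta1),
       n_sites = result$n_sites, flags = result$flags)
}

#' @export
report_list.mixture_ranking <- function(result) {
  list(type = "ranking", tied = result$tied,
       candidates = lapply(result$fits, function(f)
         report_list(f)[c("pair", "beta_hat", "se", "r_squared")]))
}

#' @export
report_list.mixture_study <- function(result) {
  list(type = "study", n_sims = result$n_sims, seed = result$seed,
       sigma = result$sigma, d = result$d, c_in = result$c_in,
       correct_rate = fmt6(result$correct_rate),
       beta_mean = fmt6(result$beta_mean),
       beta_q025 = fmt6(result$beta_q025),
       beta_q975 = fmt6(result$beta_q975))
}

#' Render a result object as a report
#'
#' Renders any of the package's result objects (`mt_lr`, `mt_search`,
#' `mixture_fit`, `mixture_ranking`, `mixture_study`) with stable field
#' ordering; floating-point values carry 6 significant digits and
#' likelihood ratios are additionally reported as log10.
#'
#' @param result A result object.
#' @param format `"text"`, `"tsv"` or `"json"`.
#' @return Character vector of report lines (a single JSON string for
#'   `"json"`). A JSON report of an `mt_lr` can be read back with
#'   [read_report()].
#' @examples
#' write_report(lr_known_contributor(freq = 1 / 11), "text")
#' @export
write_report <- function(result, format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  rl <- report_list(result)
  if (format == "json")
    return(as.character(jsonlite::toJSON(rl, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  if (format == "tsv") {
    flat <- rl[!vapply(rl, is.list, logical(1))]
    vals <- vapply(flat, function(v)
      paste(format(v, digits = 6), collapse = ","), character(1))
    return(c(paste(names(flat), collapse = "\t"),
             paste(vals, collapse = "\t")))
  }
  # text
  switch(rl$type,
    lr = c(sprintf("H_num: %s", rl$label_num),
           sprintf("H_den: %s", rl$label_den),
           sprintf("P(E|H_num) = %g, P(E|H_den) = %g",
                   rl$likelihood_num, rl$likelihood_den),
           sprintf("LR = %g", rl$lr),
           sprintf("log10(LR) = %g", rl$log10_lr)),
    deconvolution = {
      lines <- c(sprintf("status: %s (m = %d, %d solution(s))",
                         rl$status, rl$m, rl$n_solutions))
      if (rl$status == "NO_SOLUTION")
        lines <- c(lines, paste("No consistent combination found;",
                                "possible explanations include",
                                "contamination and the database not",
                                "being exhaustive."))
      c(lines, vapply(seq_along(rl$solutions), function(i)
        sprintf("solution %d: %s", i,
                paste(rl$solutions[[i]], collapse = " | ")),
        character(1)))
    },
    utils::capture.output(print(result)))
}

#' Read a JSON likelihood-ratio report back into an `mt_lr`
#'
#' @param json A JSON string produced by `write_report(x, "json")` for an
#'   `mt_lr` result.
#' @return An `mt_lr`.
#' @export
read_report <- function(json) {
  rl <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (!identical(rl$type, "lr"))
    stop("only 'lr' reports can currently be read back")
  new_lr(rl$lr, rl$likelihood_num, rl$likelihood_den,
         rl$label_num, rl$label_den,
         detail = as.list(rl$detail))
}
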