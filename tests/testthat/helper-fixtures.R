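# Shared fixture builders; everything is generated in code at test time.

write_report_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "report_id,drug_name,role,event_pt,date"
  writeLines(c(header, rows), path)
  path
}

# small normalized report frame ready for build_drug_event_matrix()
toy_records <- function(pairs) {
  data.frame(report_id = sprintf("R%03d", seq_len(nrow(pairs))),
             drug_name_raw = pairs$drug, role = "primary_suspect",
             event_pt = pairs$event, event_soc = NA_character_,
             date = "2010Q1", drug = pairs$drug,
             stringsAsFactors = FALSE)
}

toy_matrix <- function() {
  # counts {(d1,e1):2, (d1,e2):1, (d2,e1):1}
  build_drug_event_matrix(toy_records(data.frame(
    drug = c("d1", "d1", "d1", "d2"),
    event = c("e1", "e1", "e2", "e1"))), "PT")
}

ct <- function(a, b, c, d) {
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency_table")
}

# Independent brute-force oracle for the one-sided Fisher p-value: pure
# choose() enumeration of the hypergeometric support with margins fixed.
fisher_enum_greater <- function(a, b, c, d) {
  m <- a + b; k <- a + c; N <- a + b + c + d
  lo <- max(0, k - (N - m)); hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(N - m, k - xs) / choose(N, k)
  sum(probs[xs >= a])
}

# well-separated two-class descriptor matrix with named features
separable_xy <- function(n_per = 30, p = 6, gap = 4, seed = 99) {
  dilisvm:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p, gap / 2), n_per),
               matrix(rnorm(n_per * p, -gap / 2), n_per))
    colnames(x) <- sprintf("F%02d", seq_len(p))
    rownames(x) <- c(sprintf("P%03d", seq_len(n_per)),
                     sprintf("N%03d", seq_len(n_per)))
    labels <- setNames(rep(c("pos", "neg"), each = n_per), rownames(x))
    list(x = x, labels = labels)
  })
}
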