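# Build a small tract table from vectors, filling sensible defaults.
make_tracts <- function(n = NULL,
                        bc = NULL, no2 = NULL,
                        pop = NULL, nonwhite = NULL, poverty = NULL,
                        moe = NULL, ej = NULL) {
  n <- n %||% length(bc %||% no2 %||% pop)
  bc <- bc %||% seq(0.5, 1.5, length.out = n)
  no2 <- no2 %||% seq(2, 8, length.out = n)
  pop <- pop %||% rep(1000, n)
  nonwhite <- nonwhite %||% round(0.1 * pop)
  poverty <- poverty %||% round(0.1 * pop)
  moe <- moe %||% round(0.3 * pmax(poverty, 1))
  tr <- tibble::tibble(
    tract_id = sprintf("T%04d", seq_len(n)),
    bc_ugm3 = bc,
    no2_ppb = no2,
    pop_total = pop,
    pop_nonwhite = nonwhite,
    pop_poverty = poverty,
    poverty_moe = moe,
    ej_flag = FALSE,
    ej_criterion = "none"
  )
  if (!is.null(ej)) {
    tr$ej_flag <- ej
    tr$ej_criterion <- ifelse(ej, "race", "none")
    # make demographics consistent with the requested flag
    tr$pop_nonwhite <- ifelse(ej, ceiling(0.35 * tr$pop_total),
      floor(0.1 * tr$pop_total)
    )
  }
  tr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
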