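# Independent brute-force oracle for restricted least squares: solve the
# constraint system L beta = c by reparameterization (particular solution +
# nullspace basis via SVD), fit the reduced unconstrained model with
# lm.fit(), and map back.  Shares no code with the package's moment-based
# bordered-normal-equation path.
oracle_restricted <- function(y, X, L, cvec) {
  p <- ncol(X)
  Xa <- cbind(1, X)
  La <- cbind(0, L)                      # intercept unrestricted
  sv <- svd(La, nu = nrow(La), nv = p + 1)
  r <- sum(sv$d > 1e-10 * max(sv$d))
  V1 <- sv$v[, seq_len(r), drop = FALSE]
  b0 <- V1 %*% ((1 / sv$d[seq_len(r)]) *
                  (t(sv$u[, seq_len(r), drop = FALSE]) %*% cvec))
  Nmat <- sv$v[, (r + 1):(p + 1), drop = FALSE]
  Z <- Xa %*% Nmat
  zfit <- lm.fit(Z, y - drop(Xa %*% b0))
  list(beta = drop(b0 + Nmat %*% zfit$coefficients),
       sse = sum(zfit$residuals^2))
}

# random regression problem for property tests
random_problem <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", p:1)))
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p)
  y <- 1 + drop(X %*% beta) + rnorm(n)
  data.frame(y = y, X)
}

table2 <- cr_fixture("sameroff_table2")
risk_names <- table2$names[-1]
spec_m2 <- model_spec("VIQ", risk_names)
restr_all_equal <- paste(risk_names, collapse = " = ")
restr_two_group <- c("Occ = Educ = Eth = Inter",
                     "Ment = Fam = Life = Pers = Sup = Anx")
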