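## An independently written ODE-only right-hand side (no lags: transit
## pools pass straight through) used as the oracle for the DDE -> ODE
## reduction.  Organised per tissue loop, unlike the production code.
indep_ode_rhs <- function(t, y, pv) {
  q <- as.list(pv)
  nm <- names(y)
  d <- setNames(numeric(length(y)), nm)
  drink <- if (t < q$DRINKTIME) q$doserate else 0
  kge <- q$kmin + (q$kmax - q$kmin) * exp(-t / q$tau_ge)
  QliT <- q$QHe + q$Qgu

  for (chem in c("D", "M")) {
    fu <- q[[paste0("fu", chem)]]
    P <- sapply(c("fa", "spd", "rpd", "gu", "li"),
                function(tt) q[[paste0("P", tt, chem)]])
    if (chem == "D") {
      st <- c(gu = "Agu", li = "Ali", fa = "Afa", spd = "Aspd",
              rpd = "Arpd", art = "Aart", ven = "Aven")
    } else {
      st <- c(gu = "Mgu", li = "Mli", fa = "Mfa", spd = "Mspd",
              rpd = "Mrpd", art = "Mart", ven = "Mven")
    }
    Ca <- y[[st[["art"]]]] / q$Vart
    Cv <- c(fa = y[[st[["fa"]]]] / (q$Vfa * P[["fa"]]),
            spd = y[[st[["spd"]]]] / (q$Vspd * P[["spd"]]),
            rpd = y[[st[["rpd"]]]] / (q$Vrpd * P[["rpd"]]),
            gu = y[[st[["gu"]]]] / (q$Vgu * P[["gu"]]),
            li = y[[st[["li"]]]] / (q$Vli * P[["li"]]))
    Q <- c(fa = q$Qfa, spd = q$Qspd, rpd = q$Qrpd)
    for (tt in names(Q))
      d[st[[tt]]] <- Q[[tt]] * (fu * Ca - Cv[[tt]])
    d[st[["gu"]]] <- q$Qgu * (fu * Ca - Cv[["gu"]])
    d[st[["li"]]] <- q$QHe * fu * Ca + q$Qgu * Cv[["gu"]] - QliT * Cv[["li"]]
    d[st[["art"]]] <- q$QC * (y[[st[["ven"]]]] / q$Vven - Ca)
    d[st[["ven"]]] <- sum(Q * Cv[names(Q)]) + QliT * Cv[["li"]] +
      (1 - fu) * Ca * q$QC + fu * Ca * q$Qshunt -
      q$QC * y[[st[["ven"]]]] / q$Vven
  }
  CvguD <- y[["Agu"]] / (q$Vgu * q$PguD)
  CvliD <- y[["Ali"]] / (q$Vli * q$PliD)
  CvliM <- y[["Mli"]] / (q$Vli * q$PliM)
  metGu <- q$CLmet_gu_D * CvguD
  metLiD <- q$CLmet_li_D * CvliD
  metLiM <- q$CLmet_li_M * CvliM

  ## oral input, emptying, absorption (zero lags: uptake arrives at once)
  u <- q$BELLYPERM * y[["AStH"]] + q$GIPERM * y[["AGIH"]]
  ul <- q$BELLYPERMLymph * y[["AStL"]] + q$GIPERMLymph * y[["AGIL"]]
  bileD <- q$k1_DPHP_liver * y[["Ali"]]
  bileM <- q$k1_MPHP_liver * y[["Mli"]]
  d["AStH"] <- q$FracDOSEHep * drink - (kge + q$BELLYPERM) * y[["AStH"]]
  d["AGIH"] <- kge * y[["AStH"]] + bileD -
    (q$GIPERM + q$k1_DPHP_gut) * y[["AGIH"]]
  d["AStL"] <- q$FracDOSELymph * drink -
    (kge + q$BELLYPERMLymph) * y[["AStL"]]
  d["AGIL"] <- kge * y[["AStL"]] - q$GIPERMLymph * y[["AGIL"]]
  d["AupT"] <- 0
  d["AlyT"] <- 0
  d["Aly"] <- ul - q$K1Lymph * y[["Aly"]]
  d["AbiT"] <- 0
  d["Agu"] <- d[["Agu"]] + u - metGu
  d["Ali"] <- d[["Ali"]] - metLiD - bileD
  d["Aven"] <- d[["Aven"]] + q$K1Lymph * y[["Aly"]]
  d["Abw"] <- (1 - q$FracDOSEHep - q$FracDOSELymph) * drink +
    q$k1_DPHP_gut * y[["AGIH"]]
  d["MGI"] <- bileM - (q$kGa + q$k1_MPHP_gut) * y[["MGI"]]
  d["MbiT"] <- 0
  d["Mgu"] <- d[["Mgu"]] + q$kGa * y[["MGI"]] + metGu * q$rMD
  d["Mli"] <- d[["Mli"]] + metLiD * q$rMD - metLiM - bileM
  d["Mbw"] <- q$k1_MPHP_gut * y[["MGI"]]
  d["AOH"] <- q$FracMetabOH * metLiM * q$rOHM - q$K1_MOH * y[["AOH"]]
  d["Acx"] <- q$FracMetabcx * metLiM * q$rcxM - q$K1_cx * y[["Acx"]]
  d["UOH"] <- q$K1_MOH * y[["AOH"]]
  d["Ucx"] <- q$K1_cx * y[["Acx"]]
  d["Moth"] <- (1 - q$FracMetabOH - q$FracMetabcx) * metLiM
  list(unname(d))
}

state_names <- dphpk:::.state_names

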