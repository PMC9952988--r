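// Felsenstein pruning for time-reversible amino-acid models with
// discrete-gamma rate categories and an optional invariant-site class.
//
// The reversible rate matrix is passed as its (real) eigendecomposition
// Q = U diag(lambda) Uinv, obtained in R by symmetrizing with sqrt(pi).
// Analytic first derivatives are returned through the Frechet derivative of
// the matrix exponential in the eigenbasis:
//   d exp(sQ) = U ( (Uinv dQ U) o Phi_s ) Uinv,
//   Phi_s(i,j) = (e^{s li} - e^{s lj}) / (li - lj),  Phi_s(i,i) = s e^{s li}.
// Summing pattern-weighted outer products of outside (H) and inside (G)
// partials per edge gives dlnL/dP_e; projecting through Phi and the
// eigenvectors yields a single 20x20 matrix C with
//   dlnL/dtheta = <C, dQ/dtheta>,
// so exchangeability and frequency gradients cost O(1) per parameter.
//
// Node numbering follows ape's "phylo": tips 1..ntip, internals above;
// `edge` must be in postorder (children before parents).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tipstate: npat x ntip, 0-based states, -1 = missing.
// conststate: per pattern the state of a constant pattern, -1 when all
// residues are missing, -2 for a variable pattern.
// [[Rcpp::export]]
Rcpp::List cpp_plik(const arma::imat& edge,
                    const arma::vec& elen,
                    const int ntip,
                    const arma::imat& tipstate,
                    const arma::vec& weights,
                    const arma::mat& U,
                    const arma::vec& lambda,
                    const arma::mat& Uinv,
                    const arma::vec& pi,
                    const arma::vec& rates,
                    const arma::vec& ratew,
                    const double pinv,
                    const arma::ivec& conststate,
                    const bool want_grad) {
    const int nedge = edge.n_rows;
    const int npat  = tipstate.n_rows;
    const int ns    = pi.n_elem;
    const int ncat  = rates.n_elem;
    const int nnode = edge.max();
    const int nint  = nnode - ntip;
    const int root  = edge(nedge - 1, 0);
    const double wvar = 1.0 - pinv;

    vec sitelik(npat, fill::zeros);

    // inside pass (kept per category when gradients are wanted)
    std::vector<cube> part_c, msg_c;
    std::vector<cube> P_c;
    cube part(ns, npat, nint);

    for (int c = 0; c < ncat; ++c) {
        cube P(ns, ns, nedge);
        for (int e = 0; e < nedge; ++e) {
            const double s = elen(e) * rates(c);
            P.slice(e) = U * diagmat(exp(lambda * s)) * Uinv;
        }
        part.ones();
        cube msg;
        if (want_grad) msg.set_size(ns, npat, nedge);
        for (int e = 0; e < nedge; ++e) {
            const int p  = edge(e, 0);
            const int ch = edge(e, 1);
            mat m(ns, npat);
            if (ch <= ntip) {
                for (int q = 0; q < npat; ++q) {
                    const int s0 = tipstate(q, ch - 1);
                    if (s0 >= 0) m.col(q) = P.slice(e).col(s0);
                    else         m.col(q).ones();
                }
            } else {
                m = P.slice(e) * part.slice(ch - ntip - 1);
            }
            part.slice(p - ntip - 1) %= m;
            if (want_grad) msg.slice(e) = m;
        }
        rowvec Lc = pi.t() * part.slice(root - ntip - 1);
        // ratew already carries the (1 - pinv) mixture weight
        sitelik += ratew(c) * Lc.t();
        if (want_grad) {
            part_c.push_back(part);
            msg_c.push_back(msg);
            P_c.push_back(P);
        }
    }

    // invariant-site class
    if (pinv > 0.0) {
        for (int q = 0; q < npat; ++q) {
            const int s0 = conststate(q);
            if (s0 >= 0)        sitelik(q) += pinv * pi(s0);
            else if (s0 == -1)  sitelik(q) += pinv;
        }
    }

    double lnL = dot(weights, log(sitelik));

    if (!want_grad)
        return Rcpp::List::create(Rcpp::Named("loglik") = lnL,
                                  Rcpp::Named("sitelik") = sitelik);

    // outside pass + gradient accumulation
    mat W(ns, ns, fill::zeros);     // sum over edges/cats of (U'M Uinv') o Phi
    vec dpi(ns, fill::zeros);       // direct (root / invariant) frequency term
    vec dt(nedge, fill::zeros);     // branch-length gradient
    double dpinv = 0.0;

    // children edges per internal node (0-based internal index)
    std::vector<std::vector<int>> childedges(nint);
    for (int e = 0; e < nedge; ++e)
        childedges[edge(e, 0) - ntip - 1].push_back(e);
    // parent edge of each internal node, -1 for root
    std::vector<int> upedge(nint, -1);
    for (int e = 0; e < nedge; ++e)
        if (edge(e, 1) > ntip) upedge[edge(e, 1) - ntip - 1] = e;

    mat Qnorm = U * diagmat(lambda) * Uinv; // the (scaled) rate matrix itself

    for (int c = 0; c < ncat; ++c) {
        const cube& partc = part_c[c];
        const cube& msgc  = msg_c[c];
        const cube& Pc    = P_c[c];

        // coefficient per pattern for this category
        vec coef = ratew(c) * (weights / sitelik);

        // root direct frequency term
        dpi += partc.slice(root - ntip - 1) * coef;

        // outside partials, preorder (reverse postorder)
        cube O(ns, npat, nint);
        for (int q = 0; q < npat; ++q) O.slice(root - ntip - 1).col(q) = pi;
        // ensure every internal node's O is set before its children are visited:
        // iterate edges from last (root-adjacent) to first
        cube Hcube(ns, npat, nedge);
        for (int e = nedge - 1; e >= 0; --e) {
            const int p  = edge(e, 0);
            const int ch = edge(e, 1);
            const int pi0 = p - ntip - 1;
            mat H = O.slice(pi0);
            for (int e2 : childedges[pi0])
                if (e2 != e) H %= msgc.slice(e2);
            Hcube.slice(e) = H;
            if (ch > ntip)
                O.slice(ch - ntip - 1) = Pc.slice(e).t() * H;
        }

        for (int e = 0; e < nedge; ++e) {
            const int ch = edge(e, 1);
            const mat& H = Hcube.slice(e);
            // M = sum_q coef(q) * H.col(q) * G_ch.col(q)^T
            mat M(ns, ns, fill::zeros);
            if (ch <= ntip) {
                for (int q = 0; q < npat; ++q) {
                    const int s0 = tipstate(q, ch - 1);
                    if (s0 >= 0) M.col(s0) += coef(q) * H.col(q);
                    else         M += coef(q) * repmat(H.col(q), 1, ns); // rare
                }
            } else {
                M = (H.each_row() % coef.t()) * partc.slice(ch - ntip - 1).t();
            }

            // branch-length gradient: dP/dt = r_c Q P
            dt(e) += rates(c) * accu(M % (Qnorm * Pc.slice(e)));

            // Phi matrix for this edge/category
            const double s = elen(e) * rates(c);
            vec es = exp(lambda * s);
            mat Phi(ns, ns);
            for (int i = 0; i < ns; ++i) {
                for (int j = 0; j < ns; ++j) {
                    const double d = lambda(i) - lambda(j);
                    Phi(i, j) = (std::abs(d) > 1e-9)
                        ? (es(i) - es(j)) / d
                        : s * es(i);
                }
            }
            W += (U.t() * M * Uinv.t()) % Phi;
        }
    }

    // invariant-class direct terms; d sitelik/d pinv = inv_lik - gamma_mix_lik
    for (int q = 0; q < npat; ++q) {
        double invlik = 0.0;
        const int s0 = conststate(q);
        if (s0 >= 0)       invlik = pi(s0);
        else if (s0 == -1) invlik = 1.0;
        const double gmix = (wvar > 0.0)
            ? (sitelik(q) - pinv * invlik) / wvar
            : 0.0;
        dpinv += weights(q) * (invlik - gmix) / sitelik(q);
        if (pinv > 0.0 && s0 >= 0)
            dpi(s0) += pinv * weights(q) / sitelik(q);
    }

    mat C = Uinv.t() * W * U.t();  // dlnL/dQ(x,y) = C(x,y) in the original basis

    return Rcpp::List::create(Rcpp::Named("loglik") = lnL,
                              Rcpp::Named("sitelik") = sitelik,
                              Rcpp::Named("C") = C,
                              Rcpp::Named("dpi") = dpi,
                              Rcpp::Named("dt") = dt,
                              Rcpp::Named("dpinv") = dpinv);
}
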