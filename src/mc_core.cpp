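// Compiled core of the microcircuit simulator.
//
// Implements the identical synchronous tick as the pure-R reference in
// R/dynamics.R (which is the readable specification); the test suite
// asserts numerical agreement of the two paths. All randomness lives on
// the R side: this code is fully deterministic given its inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Activation {
  int code;            // 0 linear, 1 tanh, 2 sigmoid, 3 softplus, 4 scaled_tanh, 5 relu
  double beta, scale, shift;
  arma::vec slope, offset;
};

static Activation unpack_act(const List& a, int n) {
  Activation act;
  act.code = as<int>(a["code"]);
  act.beta = as<double>(a["beta"]);
  act.scale = as<double>(a["scale"]);
  act.shift = as<double>(a["shift"]);
  act.slope = as<arma::vec>(a["slope"]);
  act.offset = as<arma::vec>(a["offset"]);
  if ((int)act.slope.n_elem != n) act.slope = arma::vec(n, arma::fill::ones) * act.slope(0);
  if ((int)act.offset.n_elem != n) act.offset = arma::vec(n, arma::fill::ones) * act.offset(0);
  return act;
}

static arma::vec act_phi(const Activation& a, const arma::vec& u) {
  arma::vec x = a.slope % u + a.offset;
  switch (a.code) {
    case 0: return x;
    case 1: return arma::tanh(x);
    case 2: return 1.0 / (1.0 + arma::exp(-x));
    case 3: {
      arma::vec bx = a.beta * x;
      return (arma::max(bx, arma::zeros(bx.n_elem)) +
              arma::log1p(arma::exp(-arma::abs(bx)))) / a.beta;
    }
    case 4: return a.scale * arma::tanh(x - a.shift);
    default: {
      arma::vec r = x;
      r.elem(arma::find(x < 0)).zeros();
      return r;
    }
  }
}

static arma::vec act_phi_prime(const Activation& a, const arma::vec& u) {
  arma::vec x = a.slope % u + a.offset;
  arma::vec d;
  switch (a.code) {
    case 0: d = arma::ones(x.n_elem); break;
    case 1: d = 1.0 - arma::square(arma::tanh(x)); break;
    case 2: { arma::vec s = 1.0 / (1.0 + arma::exp(-x)); d = s % (1.0 - s); } break;
    case 3: d = 1.0 / (1.0 + arma::exp(-a.beta * x)); break;
    case 4: d = a.scale * (1.0 - arma::square(arma::tanh(x - a.shift))); break;
    default: d = arma::conv_to<arma::vec>::from(x > 0);
  }
  return a.slope % d;
}

// B_{l,m} = [1^ER_m W_{m,l} 1^RE_l]^T + Xi : padded transpose core
static void padded_transpose_into(const arma::mat& W, const arma::mat& Xi, arma::mat& B) {
  B = Xi;
  int k_src = std::min((int)B.n_cols, (int)W.n_rows);
  int k_tgt = std::min((int)B.n_rows, (int)W.n_cols);
  if (k_src > 0 && k_tgt > 0)
    B.submat(0, 0, k_tgt - 1, k_src - 1) += W.submat(0, 0, k_src - 1, k_tgt - 1).t();
}

struct Net {
  int nA, input_area, output_area;
  int rule;            // 0 dendritic (voltage mismatch), 1 error compartment
  arma::ivec nR, nE;
  double gl, grep, gerr, gden, gnudge, Cm, dt, gtot;
  arma::vec taur_r, taur_E;
  std::vector<Activation> act_r, act_e;
  std::vector<arma::mat> L_RE, L_ER;
  // forward blocks
  std::vector<int> w_tgt, w_src;
  std::vector<arma::mat> W;
  arma::vec w_eta;
  std::vector<bool> w_plastic;
  // feedback blocks
  std::vector<int> b_tgt, b_src, b_wi;
  std::vector<arma::mat> B, Xi;
};

static Net unpack_net(const List& nl) {
  Net n;
  n.nR = as<arma::ivec>(nl["n_R"]);
  n.nE = as<arma::ivec>(nl["n_E"]);
  n.nA = n.nR.n_elem;
  n.input_area = as<int>(nl["input_area"]) - 1;
  n.output_area = as<int>(nl["target_area"]) - 1;
  n.rule = as<int>(nl["rule_code"]);
  List cond = nl["cond"];
  n.gl = as<double>(cond["g_l"]);   n.grep = as<double>(cond["g_rep"]);
  n.gerr = as<double>(cond["g_err"]); n.gden = as<double>(cond["g_den"]);
  n.gnudge = as<double>(cond["g_nudge"]); n.Cm = as<double>(cond["C_m"]);
  n.gtot = n.gl + n.grep + n.gerr;
  n.dt = as<double>(nl["dt"]);
  n.taur_r = as<arma::vec>(nl["taur_r"]);
  n.taur_E = as<arma::vec>(nl["taur_E"]);
  List ar = nl["act_r_packed"], ae = nl["act_e_packed"];
  List lre = nl["L_RE"], ler = nl["L_ER"];
  for (int l = 0; l < n.nA; ++l) {
    n.act_r.push_back(unpack_act(ar[l], n.nR(l)));
    n.act_e.push_back(unpack_act(ae[l], n.nE(l)));
    n.L_RE.push_back(as<arma::mat>(lre[l]));
    n.L_ER.push_back(as<arma::mat>(ler[l]));
  }
  List Wl = nl["W"];
  for (int i = 0; i < Wl.size(); ++i) {
    List blk = Wl[i];
    n.w_tgt.push_back(as<int>(blk["tgt"]) - 1);
    n.w_src.push_back(as<int>(blk["src"]) - 1);
    n.W.push_back(as<arma::mat>(blk["mat"]));
    n.w_plastic.push_back(as<bool>(blk["plastic"]));
  }
  n.w_eta = arma::vec(n.W.size());
  for (size_t i = 0; i < n.W.size(); ++i) n.w_eta(i) = as<double>(as<List>(Wl[i])["eta"]);
  List Bl = nl["B"];
  for (int i = 0; i < Bl.size(); ++i) {
    List blk = Bl[i];
    n.b_tgt.push_back(as<int>(blk["tgt"]) - 1);
    n.b_src.push_back(as<int>(blk["src"]) - 1);
    n.b_wi.push_back(as<int>(blk["w_index"]) - 1);
    n.B.push_back(as<arma::mat>(blk["mat"]));
    n.Xi.push_back(as<arma::mat>(blk["Xi"]));
  }
  return n;
}

struct State {
  std::vector<arma::vec> u_som, du_som, u_pred, u_err, u_breve, r_r, phi_p,
                         e_som, de_som, e_prosp, r_E;
};

static std::vector<arma::vec> unpack_veclist(const List& l) {
  std::vector<arma::vec> out;
  for (int i = 0; i < l.size(); ++i) out.push_back(as<arma::vec>(l[i]));
  return out;
}

static State unpack_state(const List& sl) {
  State s;
  s.u_som = unpack_veclist(sl["u_som"]);   s.du_som = unpack_veclist(sl["du_som"]);
  s.u_pred = unpack_veclist(sl["u_pred"]); s.u_err = unpack_veclist(sl["u_err"]);
  s.u_breve = unpack_veclist(sl["u_breve"]); s.r_r = unpack_veclist(sl["r_r"]);
  s.phi_p = unpack_veclist(sl["phi_p"]);
  s.e_som = unpack_veclist(sl["e_som"]);   s.de_som = unpack_veclist(sl["de_som"]);
  s.e_prosp = unpack_veclist(sl["e_prosp"]); s.r_E = unpack_veclist(sl["r_E"]);
  return s;
}

static List pack_veclist(const std::vector<arma::vec>& v) {
  List l(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    l[i] = NumericVector(v[i].begin(), v[i].end());   // plain vector, no dim
  return l;
}

static List pack_state(const State& s) {
  List out = List::create(
    _["u_som"] = pack_veclist(s.u_som), _["du_som"] = pack_veclist(s.du_som),
    _["u_pred"] = pack_veclist(s.u_pred), _["u_err"] = pack_veclist(s.u_err),
    _["u_breve"] = pack_veclist(s.u_breve), _["r_r"] = pack_veclist(s.r_r),
    _["phi_p"] = pack_veclist(s.phi_p),
    _["e_som"] = pack_veclist(s.e_som), _["de_som"] = pack_veclist(s.de_som),
    _["e_prosp"] = pack_veclist(s.e_prosp), _["r_E"] = pack_veclist(s.r_E));
  out.attr("class") = "mc_state";
  return out;
}

// one synchronous tick; target may be empty (no nudging)
static void tick(Net& net, State& st, const arma::vec& input,
                 const arma::vec& target, bool nudge, bool plasticity,
                 long tick_no) {
  int nA = net.nA;
  std::vector<arma::vec> r_prev = st.r_r;
  std::vector<arma::vec> rE_prev = st.r_E;

  // (1) dendritic drives from previous-tick quantities
  std::vector<arma::vec> u_pred(nA), u_err(nA), dend(nA);
  for (int l = 0; l < nA; ++l) {
    u_pred[l] = arma::zeros(net.nR(l));
    u_err[l] = arma::zeros(net.nR(l));
  }
  for (size_t i = 0; i < net.W.size(); ++i)
    u_pred[net.w_tgt[i]] += net.W[i] * r_prev[net.w_src[i]];
  for (int l = 0; l < nA; ++l)
    if (net.nE(l) > 0) u_err[l] = net.L_RE[l] * rE_prev[l];
  for (int l = 0; l < nA; ++l) {
    if (net.nE(l) == 0) { dend[l] = arma::vec(); continue; }
    arma::vec e_rep = net.L_ER[l] * st.phi_p[l];
    if (l == net.output_area) {
      dend[l] = nudge ? arma::vec(e_rep % (target - r_prev[l]))
                      : arma::zeros(net.nE(l));
    } else {
      arma::vec e_err = arma::zeros(net.nE(l));
      for (size_t i = 0; i < net.B.size(); ++i)
        if (net.b_tgt[i] == l) e_err += net.B[i] * rE_prev[net.b_src[i]];
      dend[l] = e_rep % e_err;
    }
  }

  // (2)+(3) representation somata, prospective rates
  for (int l = 0; l < nA; ++l) {
    st.u_pred[l] = u_pred[l];
    st.u_err[l] = u_err[l];
    if (l == net.input_area) {
      st.u_som[l] = input;
      st.du_som[l] = arma::zeros(net.nR(l));
      st.u_breve[l] = input;
      st.r_r[l] = input;                       // rates clamped to the input
      st.phi_p[l] = act_phi_prime(net.act_r[l], input);
    } else {
      arma::vec du = (-net.gl * st.u_som[l]
                      - net.grep * (st.u_som[l] - u_pred[l])
                      - net.gerr * (st.u_som[l] - u_err[l])) / net.Cm;
      st.u_som[l] += net.dt * du;
      if (!st.u_som[l].is_finite())
        stop("non-finite somatic voltage (tick %d, area %d)", tick_no, l + 1);
      // stored derivative: analytic rhs at the updated voltage (see R ref.)
      arma::vec du_new = (-net.gl * st.u_som[l]
                          - net.grep * (st.u_som[l] - u_pred[l])
                          - net.gerr * (st.u_som[l] - u_err[l])) / net.Cm;
      st.du_som[l] = du_new;
      st.u_breve[l] = st.u_som[l] + net.taur_r(l) * du_new;
      st.r_r[l] = act_phi(net.act_r[l], st.u_breve[l]);
      st.phi_p[l] = act_phi_prime(net.act_r[l], st.u_breve[l]);
    }
  }

  // error populations
  for (int l = 0; l < nA; ++l) {
    if (net.nE(l) == 0) continue;
    double g_c = (l == net.output_area) ? net.gnudge : net.gden;
    arma::vec de = (-net.gl * st.e_som[l] - g_c * (st.e_som[l] - dend[l])) / net.Cm;
    st.e_som[l] += net.dt * de;
    if (!st.e_som[l].is_finite())
      stop("non-finite error voltage (tick %d, area %d)", tick_no, l + 1);
    st.de_som[l] = de;
    arma::vec de2 = (-net.gl * st.e_som[l] - g_c * (st.e_som[l] - dend[l])) / net.Cm;
    st.e_prosp[l] = st.e_som[l] + net.taur_E(l) * de2;
    st.r_E[l] = act_phi(net.act_e[l], st.e_prosp[l]);
  }

  // (4) plasticity and feedback refresh
  if (plasticity) {
    double lam = net.grep / net.gtot;
    for (size_t i = 0; i < net.W.size(); ++i) {
      if (!net.w_plastic[i] || net.w_eta(i) == 0) continue;
      int l = net.w_tgt[i];
      arma::vec post = (net.rule == 1)
        ? arma::vec((net.gerr / net.gtot) * st.u_err[l])
        : arma::vec(st.u_breve[l] - lam * st.u_pred[l]);
      net.W[i] += (net.w_eta(i) * net.dt) * (post * r_prev[net.w_src[i]].t());
    }
    for (size_t i = 0; i < net.B.size(); ++i)
      padded_transpose_into(net.W[net.b_wi[i]], net.Xi[i], net.B[i]);
  }
}

// run a sequence of items: for each, settle (plasticity off), then present
// T_ticks with optional plasticity; state persists across items.
// items: list(input (d x F), target (vec, may be length 0), active_from,
//             T_ticks); active_from: 1 = always (incl. settling),
//             k > 1 = from presentation tick k on, -1 = never.
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List net_list, List state_list, List items, bool plasticity,
             int settle_ticks) {
  Net net = unpack_net(net_list);
  State st = unpack_state(state_list);
  int n_items = items.size();
  int n_out = net.nR(net.output_area);
  arma::mat outputs(n_out, n_items, arma::fill::zeros);
  long tick_no = 0;

  for (int it = 0; it < n_items; ++it) {
    List item = items[it];
    arma::mat inp = as<arma::mat>(item["input"]);
    arma::vec tgt = as<arma::vec>(item["target"]);
    int active_from = as<int>(item["active_from"]);
    int T = as<int>(item["T_ticks"]);
    bool has_tgt = tgt.n_elem > 0 && active_from > 0;

    for (int s = 0; s < settle_ticks; ++s)
      tick(net, st, inp.col(0), tgt, has_tgt && active_from == 1, false, ++tick_no);
    for (int t = 1; t <= T; ++t) {
      int fcol = std::min(t, (int)inp.n_cols) - 1;
      bool nudge = has_tgt && t >= active_from;
      tick(net, st, inp.col(fcol), tgt, nudge, plasticity, ++tick_no);
    }
    outputs.col(it) = st.r_r[net.output_area];
  }

  List Wout(net.W.size()), Bout(net.B.size());
  for (size_t i = 0; i < net.W.size(); ++i) Wout[i] = wrap(net.W[i]);
  for (size_t i = 0; i < net.B.size(); ++i) Bout[i] = wrap(net.B[i]);
  return List::create(_["W"] = Wout, _["B"] = Bout,
                      _["state"] = pack_state(st),
                      _["outputs"] = outputs.t());
}
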