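"""Regenerate inst/extdata wavelet tables.

Filters for the bior/coif/db/rbio/sym/haar families are the canonical
coefficients as distributed by PyWavelets.  The discrete Meyer (dmey)
filter is built here directly: a 102-tap FIR approximation obtained by
frequency-sampling the Meyer conjugate mirror filter and then refining
the taps so the double-shift orthonormality conditions hold to machine
precision (Gauss-Newton on the underdetermined system).  Only the
decomposition filters are stored; the reconstruction filters follow from
the quadrature-mirror relations

    rec_lo[n] = (-1)^(n+1) * dec_hi[n]
    rec_hi[n] = (-1)^n     * dec_lo[n]

which hold exactly for every filter written here.

Run from the repository root:  python data-raw/make_filters.py
"""
import numpy as np
import pywt
from scipy.optimize import least_squares

DMEY_LEN = 102


def make_dmey(n_taps=DMEY_LEN, grid=1 << 18):
    """102-tap orthonormal FIR approximation of the Meyer scaling filter."""

    def nu(x):
        x = np.clip(x, 0, 1)
        return x ** 4 * (35 - 84 * x + 70 * x ** 2 - 20 * x ** 3)

    def phihat(w):
        w = np.abs(w)
        out = np.zeros_like(w)
        out[w <= 2 * np.pi / 3] = 1.0
        m = (w > 2 * np.pi / 3) & (w < 4 * np.pi / 3)
        out[m] = np.cos(np.pi / 2 * nu(3 * w[m] / (2 * np.pi) - 1))
        return out

    om = -np.pi + 2 * np.pi * np.arange(grid) / grid
    m0 = np.sqrt(2) * sum(phihat(2 * (om + 2 * np.pi * k)) for k in (-1, 0, 1))
    # half-sample-symmetric extraction of n_taps coefficients
    ns = np.arange(-n_taps // 2, n_taps // 2) + 0.5
    E = np.exp(1j * np.outer(om, ns))
    h0 = (m0[:, None] * E).mean(axis=0).real

    L = n_taps

    def orth_resid(h):
        r = [np.dot(h, h) - 1.0]
        for k in range(1, L // 2):
            r.append(np.dot(h[2 * k:], h[:L - 2 * k]))
        r.append(h.sum() - np.sqrt(2))
        return np.array(r)

    sol = least_squares(orth_resid, h0, method="trf",
                        xtol=3e-16, ftol=3e-16, gtol=3e-16, max_nfev=200)
    h = sol.x
    assert np.max(np.abs(orth_resid(h))) < 1e-12
    return h


FAMILIES = {
    "bior": ["bior1.1", "bior1.3", "bior1.5", "bior2.2", "bior2.4", "bior2.6",
             "bior2.8", "bior3.1", "bior3.3", "bior3.5", "bior3.7", "bior3.9",
             "bior4.4", "bior5.5", "bior6.8"],
    "coif": ["coif%d" % i for i in range(1, 6)],
    "db":   ["db%d" % i for i in range(1, 11)],
    "rbio": ["rbio1.1", "rbio1.3", "rbio1.5", "rbio2.2", "rbio2.4", "rbio2.6",
             "rbio2.8", "rbio3.1", "rbio3.3", "rbio3.5", "rbio3.7", "rbio3.9",
             "rbio4.4", "rbio5.5", "rbio6.8"],
    "sym":  ["sym%d" % i for i in range(2, 9)],
    "dmey": ["dmey"],
    "haar": ["haar"],
}


def filters_for(name):
    if name == "dmey":
        h = make_dmey()
        n = np.arange(len(h))
        g = ((-1.0) ** (n + 1)) * h[::-1]
        return h, g, None
    w = pywt.Wavelet(name)
    vm = w.vanishing_moments_psi
    return np.array(w.dec_lo), np.array(w.dec_hi), vm


with open("inst/extdata/wavelet_filters.csv", "w") as fh:
    fh.write("wavelet,filter,idx,value\n")
    for fam, members in FAMILIES.items():
        for name in members:
            lo, hi, _ = filters_for(name)
            for fname, coefs in (("dec_lo", lo), ("dec_hi", hi)):
                for i, c in enumerate(coefs):
                    fh.write("%s,%s,%d,%.17g\n" % (name, fname, i + 1, c))

with open("inst/extdata/wavelet_catalog.csv", "w") as fh:
    fh.write("wavelet,family,filter_length,vanishing_moments\n")
    for fam, members in FAMILIES.items():
        for name in members:
            lo, hi, vm = filters_for(name)
            fh.write("%s,%s,%d,%s\n" % (name, fam, len(lo),
                                        "NA" if vm is None else vm))
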