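"""Independent MFCC reference implementation (numpy/scipy).

Reads a job description JSON naming raw float64 sample files and the
extraction dialect, computes MFCCs with an implementation that shares no
code with the R package (numpy FFT, scipy DCT), and writes each result as
row-major float64 binary. Used only as a cross-language oracle by the test
suite and never by the package itself.

Usage: python mfcc_oracle.py <job.json>
"""
import json
import sys

import numpy as np
from scipy.fft import dct


def mel_constant(f0):
    return 1000.0 / np.log10(1.0 + 1000.0 / f0)


def hz_to_mel(f, f0):
    return mel_constant(f0) * np.log10(1.0 + np.asarray(f, float) / f0)


def mel_to_hz(m, f0):
    return f0 * (10.0 ** (np.asarray(m, float) / mel_constant(f0)) - 1.0)


def mfcc(x, sr, d):
    n_fft = int(d["n_fft"])
    hop = int(d["hop_length"])
    alpha = float(d["preemphasis"])
    n_mels = int(d["n_mels"])
    n_mfcc = int(d["n_mfcc"])
    f0 = float(d["corner_frequency_hz"])
    fmin = float(d["fmin"])
    fmax = d.get("fmax")
    fmax = sr / 2.0 if fmax is None else float(fmax)
    floor_rel = float(d["floor_rel"])

    # pre-emphasis
    y = np.empty_like(x)
    y[0] = x[0]
    y[1:] = x[1:] - alpha * x[:-1]

    # framing with zero end-padding
    L = len(y)
    if L <= n_fft:
        n_frames = 1
    else:
        n_frames = 1 + int(np.ceil((L - n_fft) / hop))
    need = n_fft + (n_frames - 1) * hop
    if need > L:
        y = np.concatenate([y, np.zeros(need - L)])
    frames = np.stack([y[i * hop:i * hop + n_fft] for i in range(n_frames)])

    # periodic Hann window
    k = np.arange(n_fft)
    frames = frames * (0.5 - 0.5 * np.cos(2.0 * np.pi * k / n_fft))

    spec = np.abs(np.fft.rfft(frames, n=n_fft, axis=1)) ** 2

    # triangular mel filter bank evaluated on the FFT bin grid
    n_bins = n_fft // 2 + 1
    bin_hz = np.arange(n_bins) * sr / n_fft
    mel_pts = np.linspace(hz_to_mel(fmin, f0), hz_to_mel(fmax, f0),
                          n_mels + 2)
    hz_pts = mel_to_hz(mel_pts, f0)
    fb = np.zeros((n_mels, n_bins))
    for m in range(n_mels):
        lo, ce, hi = hz_pts[m], hz_pts[m + 1], hz_pts[m + 2]
        up = (bin_hz - lo) / (ce - lo)
        down = (hi - bin_hz) / (hi - ce)
        fb[m] = np.maximum(0.0, np.minimum(up, down))

    energy = spec @ fb.T
    mx = energy.max()
    eps = mx * floor_rel if mx > 0 else np.finfo(float).tiny
    loge = np.log10(np.maximum(energy, eps))

    return dct(loge, type=2, norm="ortho", axis=1)[:, :n_mfcc]


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    d = job["dialect"]
    for clip in job["clips"]:
        x = np.fromfile(clip["samples"], dtype="<f8")
        out = mfcc(x, float(clip["sample_rate"]), d)
        out.astype("<f8").tofile(clip["out"])


if __name__ == "__main__":
    main(sys.argv[1])
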