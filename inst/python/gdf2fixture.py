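#!/usr/bin/env python
"""Convert BCI Competition IV-2b style GDF recordings to the midecoder
plain-text fixture format (per-subject signals CSV + JSON manifest).

Usage: python gdf2fixture.py IN_PATH OUT_DIR

IN_PATH is a .gdf file or a directory of them. File names are expected to
follow the competition convention B0102T.gdf (subject 01, session 02,
T=training/E=evaluation). Requires the `mne` library. Trials are epoched
to [0, 8) s from trial start (cue at 3 s); left/right labels come from
event codes 769/770. Trials with rejection markers are kept.
"""
import csv
import json
import os
import re
import sys
from collections import defaultdict


def convert(paths, out_dir):
    import mne
    import numpy as np

    os.makedirs(out_dir, exist_ok=True)
    per_subject = defaultdict(list)
    for path in paths:
        m = re.match(r"B(\d{2})(\d{2})[TE]", os.path.basename(path))
        if not m:
            raise SystemExit(f"unrecognised file name: {path}")
        subject, session = f"S{int(m.group(1)):02d}", int(m.group(2))
        raw = mne.io.read_raw_gdf(path, preload=True, verbose="error")
        fs = raw.info["sfreq"]
        events, event_id = mne.events_from_annotations(raw, verbose="error")
        codes = {}
        for name, code in event_id.items():
            if name in ("769", "cue left", "Left"):
                codes[code] = "left"
            if name in ("770", "cue right", "Right"):
                codes[code] = "right"
        picks = [ch for ch in raw.ch_names if "EOG" not in ch.upper()][:3]
        data = raw.get_data(picks=picks) * 1e6  # volts -> microvolts
        n = int(round(8 * fs))
        trial_idx = 0
        for sample, _, code in events:
            if code not in codes:
                continue
            start = int(sample - 3 * fs)  # cue is 3 s after trial start
            if start < 0 or start + n > data.shape[1]:
                continue
            trial_idx += 1
            per_subject[subject].append(
                dict(session=session, trial=trial_idx, fs=fs,
                     label=codes[code], data=data[:, start:start + n]))
    for subject, trials in per_subject.items():
        with open(os.path.join(out_dir, f"{subject}_signals.csv"), "w",
                  newline="") as fh:
            w = csv.writer(fh)
            w.writerow(["session", "trial", "sample", "C3", "Cz", "C4"])
            for t in trials:
                for i in range(t["data"].shape[1]):
                    w.writerow([t["session"], t["trial"], i,
                                repr(t["data"][0, i]), repr(t["data"][1, i]),
                                repr(t["data"][2, i])])
        manifest = dict(
            format="midecoder-fixture", version=1, subject=subject,
            sampling_rate=trials[0]["fs"], n_samples=trials[0]["data"].shape[1],
            trials=[dict(session=t["session"], trial=t["trial"],
                         label=t["label"]) for t in trials])
        with open(os.path.join(out_dir, f"{subject}_manifest.json"), "w") as fh:
            json.dump(manifest, fh)


if __name__ == "__main__":
    if len(sys.argv) != 3:
        raise SystemExit(__doc__)
    src, out_dir = sys.argv[1], sys.argv[2]
    if os.path.isdir(src):
        paths = sorted(os.path.join(src, f) for f in os.listdir(src)
                       if f.lower().endswith(".gdf"))
    else:
        paths = [src]
    if not paths:
        raise SystemExit(f"no .gdf files under {src}")
    convert(paths, out_dir)
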