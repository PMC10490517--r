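# canonical channel and session naming shared across the package

SYNC_COLUMNS <- c("time", "Fp1", "Fp2", "C3", "C4", "O1", "O2",
                  "SPR1", "SPR2", "ECG1", "ECG2")
EEG_CHANNELS <- c("Fp1", "Fp2", "C3", "C4", "O1", "O2")
SPR_CHANNELS <- c("SPR1", "SPR2")
ECG_CHANNELS <- c("ECG1", "ECG2")
SESSION_LEVELS <- c("Manual1", "Manual2", "Manual3", "ADAS")
CLEAN_CHANNELS <- c(EEG_CHANNELS, "SPR", "ECG")
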