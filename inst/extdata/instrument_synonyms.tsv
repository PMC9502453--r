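synonym	canonical
ESI-QFT	LC-ESI-QFT
LC-ESI-QFT	LC-ESI-QFT
ESI-QTOF	LC-ESI-QTOF
ESI-QQTOF	LC-ESI-QTOF
Q-TOF	LC-ESI-QTOF
QTOF	LC-ESI-QTOF
LC-Q-TOF/MS	LC-ESI-QTOF
LC-ESI-QTOF	LC-ESI-QTOF
ESI-ITFT	LC-ESI-ITFT
LC-ESI-ITFT	LC-ESI-ITFT
ESI-IT	LC-ESI-IT
LC-ESI-IT	LC-ESI-IT
ESI-QQ	LC-ESI-QQ
LC-ESI-QQ	LC-ESI-QQ
ESI-TOF	LC-ESI-TOF
LC-ESI-TOF	LC-ESI-TOF
ESI-QQQ	LC-ESI-QQ
HPLC-ESI-TOF	LC-ESI-TOF
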