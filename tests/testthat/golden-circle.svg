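<svg xmlns="http://www.w3.org/2000/svg" width="600.00" height="620.00" viewBox="0 0 600.00 620.00">
<rect x="0" y="0" width="600.00" height="620.00" fill="white"/>
<text x="300.00" y="20" font-size="14" text-anchor="middle" font-family="sans-serif">Pham 1</text>
<circle cx="300.00" cy="300.00" r="210.00" fill="none" stroke="#CCCCCC" stroke-width="1"/>
<path d="M 300.00 90.00 Q 322.73 286.88 481.87 405.00" fill="none" stroke="#0000CC" stroke-width="2.68" stroke-opacity="0.65"/>
<path d="M 300.00 90.00 Q 277.27 286.88 118.13 405.00" fill="none" stroke="#0000CC" stroke-width="2.63" stroke-opacity="0.65"/>
<path d="M 481.87 405.00 Q 300.00 326.25 118.13 405.00" fill="none" stroke="#0000CC" stroke-width="2.68" stroke-opacity="0.65"/>
<circle cx="300.00" cy="90.00" r="4" fill="#E66767" stroke="black" stroke-width="0.5"/>
<text x="300.00" y="81.00" font-size="10" text-anchor="start" font-family="sans-serif" font-weight="bold">SynPhage01 (1,5)</text>
<circle cx="481.87" cy="405.00" r="4" fill="#E66767" stroke="black" stroke-width="0.5"/>
<text x="492.26" y="414.00" font-size="10" text-anchor="start" font-family="sans-serif" font-weight="bold">SynPhage02 (4)</text>
<circle cx="118.13" cy="405.00" r="4" fill="#E66767" stroke="black" stroke-width="0.5"/>
<text x="107.74" y="414.00" font-size="10" text-anchor="end" font-family="sans-serif" font-weight="bold">SynPhage03 (3)</text>
</svg>
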