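You are assisting a nuclear medicine department with PET-CT radiology reports.
Your task is to classify the report below for the presence or absence of one or more actionable incidental findings (AIFs): findings unrelated to the reason for the scan that require clinical action or follow-up. Work step by step: first extract every sentence in the report that describes an actionable incidental finding, copying each sentence verbatim, and then decide the document label from the sentences you extracted.
Answer with a first line of the form "Actionable findings present: yes" or "Actionable findings present: no", followed by the extracted sentences, one per line. If the report contains no actionable incidental findings, write NONE on the second line.

Report:
<REPORT TEXT HERE>
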