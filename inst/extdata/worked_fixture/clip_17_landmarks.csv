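"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.29,26.05,25.11,27.54,34.42,38.61,42.66,51.2,55.02,62.74,68.65,73.4,79,84.41,87.21,88.03,88.64,28.5,33.34,39.98,43.72,47.97,65.95,67.53,73.27,79.08,85.44,56.49,54.25,56.1,54.03,48.5,49.79,56.84,61.01,64.4,44.61,40.19,34.82,30.77,34.54,40.69,81.72,77.81,70.48,68.15,72.11,78.02,71.25,68.8,65.01,57.95,46.59,42.21,41.81,42.34,48.47,58.36,63.27,68.53,64.15,64.07,58.16,49.49,46.99,48.76,55.73,60.34,51.2,58.02,68,76.64,79.41,85.77,88.47,90.72,90.63,93.47,90.83,85.41,81.9,74.72,67.21,60.3,52.2,34.17,31.61,31.19,31.38,31.68,34.37,33.6,29.57,33.09,34.41,40.72,44.3,52.69,55.13,59.47,62.43,61.62,60.56,60.16,39.76,39.69,40.44,40.26,44.86,44.73,40.64,37.75,40.74,41.11,42.7,43.5,74.83,71.21,70.93,70.36,69.22,73.93,76.86,80.45,82.37,88.22,84.48,78.34,75.81,72.11,72.83,73.88,76.68,79.44,79.67,77.2
2,24.95,25.33,26.81,28.86,33.24,38.51,43.74,51.89,57.24,65.01,69.53,75.4,80.65,84.12,87.41,91.06,91.42,32.15,34.74,39.19,45.29,46.51,67.48,70.13,76.38,79.85,83.3,57.21,58.25,58.6,59.21,50.2,51.86,57.69,63.41,65.16,45.12,41.22,38.03,32.7,37.27,41.07,83.26,79.11,71.19,69.64,71.91,77.12,71.67,69.47,64.33,60.66,49.86,44.59,42.66,44.91,50.42,58.52,65.21,71.58,67.38,63.01,56.86,52.02,46.98,51.69,56.47,62.63,49.73,55.5,67.79,73.35,74.94,82.44,85.73,88.61,89.2,88.52,86.83,83.73,78.76,71.09,62.82,57.27,49.93,31.73,27.73,27.6,26.88,30.15,29.21,28.87,30.35,29.04,31.55,37.53,41.96,49.59,50.87,58.16,58.39,58.07,58.29,56.9,38.58,35.24,37.13,38.62,41.37,38.07,38.74,36.22,38.03,38.72,42.98,40.47,73.1,67.08,66.62,65.59,66.42,72.07,74.77,76.87,78.99,82.38,78.52,76.43,73.28,70.23,68.73,72.67,75.14,78.61,78.57,75.46
3,27.23,27.34,29.03,28.16,35.32,39.98,43.28,50.16,58.65,64.76,69.69,74.46,79.34,85.95,88.44,89.48,90.29,30.5,36.63,39.98,44.82,48.61,67.85,72.56,76.96,79.32,87.19,57.26,58.43,58.83,58.15,50.28,49.85,57.7,62.95,66.03,46.83,42.72,36.24,33.22,37.11,42.05,84.91,79.96,71.08,71.76,72.54,78.81,72,70.38,66.21,56.85,50.34,45.57,45.5,44.38,51.36,56.74,66.88,70.62,66.44,64.65,57.67,53.16,47.57,53.69,57.61,64.87,47.74,56.63,66.27,71.17,77.21,82.95,86.82,90.58,89.16,88,88.32,84.15,80.17,72.47,64.66,57.77,50.25,30.97,28.12,29.62,29.51,29.38,30.87,29.31,29.18,28.49,31.53,37.12,43.32,49.95,52.47,56.92,57.61,60.3,60.11,58.8,39.44,37.39,37.3,37.92,40.87,41.15,39.04,34.96,36.34,40.04,42.4,43.61,76.08,70.22,69.16,67.14,67.29,71.68,75.24,77.5,81.93,83.37,80.73,76.09,72.58,70.17,70.08,71.31,75.33,74.93,79.47,75.69
4,25.98,27.03,28.13,30.66,36.47,41.62,44.92,53.05,59.97,66.63,72.2,77.96,83.45,86.94,87.02,91.14,93.17,32.36,40.7,41.95,47.81,49.44,66.97,72.23,78.11,81.94,87.07,60.08,59.75,60.55,60.64,52.19,52.75,58.09,62.47,67.14,49.67,44.87,38.11,35.16,37.26,43.6,83.69,79.55,73.52,72.21,75.93,81.4,73.1,70.34,66.93,58.61,51.49,46.7,46.81,46.09,53.07,61.52,68.65,73.05,66.33,64.79,57.52,52.54,48.9,54.71,59.96,65.13,48.37,57.84,64.94,72.27,77.06,83.79,88.15,90.12,88.89,88.22,88.81,84.24,77.17,70.08,66.41,59.46,51.1,30.14,30.49,28.87,29.39,32.11,31.45,28.9,28.06,28.62,28.84,38.56,43,50.61,53.94,57.56,58.56,58.84,55.9,57.22,39.87,36.04,37.29,38.02,41,40.78,39.87,37.11,35.61,38.24,41.93,41.03,74.95,68.57,66.77,66,68.2,70.09,75.33,78.77,80.86,82.32,79.97,77.03,71.77,71.45,69.26,70.97,74.9,75.29,77.57,76.44
5,21.83,24.53,24.92,28.13,32.17,37.43,41.22,47.87,55.9,60.83,66.81,72.05,77.49,82.12,84.02,87.51,87.68,26.65,31.57,36.38,43.02,45.83,65.31,68.35,74.6,77.8,82.96,54.68,55.79,56.56,55.47,47.59,51.43,55.07,59.41,63.29,43.31,39.53,36.05,31.82,34.84,41.53,80.36,75.43,68.2,65.59,72.47,76.64,68.88,67.19,62.15,54.37,48.63,42.2,40.44,42,48.11,54.02,64.86,67.46,63.56,61.77,54.36,48.57,47.94,50.01,52.63,61.23,48.22,54.45,63.67,70.99,77.16,79.79,85.36,87.33,88.65,86.99,84.96,81.12,77.06,68.66,64.8,55.15,47.76,30.05,25.97,26.05,29.45,30.11,29.38,28.96,27.2,26.95,28.13,36.65,40.43,48.77,51.1,55.44,55.85,56.52,55.09,53.52,37.99,35.68,36.13,37.25,38.09,38.06,38.16,34.9,34.33,36.01,38.15,38.02,72.48,67.17,65.52,64.85,64.64,70.39,71.94,75.05,79.15,81.44,78.32,73.43,71.37,69.12,66.74,66.18,71.69,72.14,75.69,73.04
6,22.79,23.74,23.95,27.66,30.98,38.05,42.83,48.74,55.5,59.42,67.22,73.48,78.75,82.35,83.89,86.64,87.34,26.03,31.9,37.97,41.44,46.09,64.82,66.88,73.17,75.8,82.78,53.41,54.63,56.63,56.29,47.44,51.15,53.6,59.21,61.13,40.78,39.01,33.88,30.28,33.6,40.02,80.68,76.95,70.38,66.13,68.52,76.64,69.66,67.35,64.23,55.28,46.22,39.95,40.95,40.67,47.09,53.81,62.85,68.24,61.47,60.71,55.76,48.87,45.85,49.77,52.65,60.81,50.37,57.58,67.35,73.74,79.99,83.94,89.01,89.36,90.44,90.44,87.62,84.4,81.64,72.6,66.16,58.75,52.38,34.22,30.32,30.45,31.32,33.92,32.75,29.73,28.89,30.57,34.63,38.47,46.07,52.26,55.93,59.17,62.56,61.67,59.91,57.05,38.79,40.93,39.46,39.61,42.01,41.54,40.31,37.44,38.37,39.67,42.78,40.8,74.41,71.16,69.78,68.84,67.58,71.71,78.27,79.51,81.92,82.14,82.94,77.99,73.55,71.55,73.39,73.81,77.51,78.25,80.58,77.41
7,22.93,24.79,25.15,28.93,32.62,38.61,42.21,50.64,57.41,63.49,68.94,76.09,79.44,84.53,87.07,87.56,90.74,28.45,33.32,38.16,43.97,46.94,65.71,68.9,75.45,79.33,83.82,55.73,55.75,58.05,54.83,49.84,52.48,55.05,60.79,64.42,45.9,41.78,36.1,31.28,35.59,40.96,82.37,76.77,72.77,68.36,72.11,79.18,70.45,66.89,66,56.86,48.02,43.24,42.05,41.64,49.88,54.51,65.85,67.12,64.47,63.09,55.71,50.23,48.68,51.1,56.41,62.37,50.71,61.86,67.74,74.76,80.81,84.68,89.45,92.66,89.55,90.69,88.73,86.18,82.72,72.42,68.78,60.63,53.07,31.86,30.04,31.1,31.42,33.77,35.72,31.99,31.87,31.63,32.91,39.55,48.2,52.94,56.04,59.16,62.01,61.31,62.23,61.13,40.01,39.88,41.52,38.19,43.79,41.89,41.82,39.99,38.94,40.8,42.55,42.49,77.26,71.38,69.86,68.02,66.65,73.74,77.45,78.11,82.87,85.43,82.1,77.2,76.82,71.89,73.7,75.06,77.48,78.36,79.75,80.05
8,22.64,22.55,24.13,26.95,32.29,38.27,41.7,49.7,55.8,62.38,66.53,73.68,78.93,85.54,86.47,88.36,88.13,29.57,33.06,37.49,44.13,48.23,64.29,70.55,76.33,78.91,82.71,55.02,54.51,58.13,57.03,47.15,51.13,56.82,58.78,62.03,43.78,41.56,35.1,31.4,34.61,38.92,80.67,76.12,70.43,68.77,69.76,77.31,68.66,67.61,63.82,56.28,48.48,45.7,42.29,42.06,49.59,55.84,64.2,67.4,67.47,63.7,56.07,48.36,45.14,49.82,56.1,60.88,51.14,59.51,68.23,76.09,79.27,84.34,89.42,92.18,91.53,91.37,89.39,86.64,80.63,72.46,66.43,59.8,52.78,32.28,30.19,30.1,30.71,31.59,32.44,30.97,30.85,30.58,33.98,42,43.71,50.91,55.05,59.86,59.7,62.34,59.91,59.7,40.69,40.82,40.31,40.43,42.78,43.23,40.16,35.65,37.62,40.84,43.64,41.64,75.59,71.46,69.99,68.37,68.38,72.07,76.52,80.24,84.13,85.34,82.89,79.48,76.85,73.71,72.25,74.11,77.27,78.16,80.29,78.46
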